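#' Configuration for the synthetic nCounter data generator
#'
#' Defines the simulated study conditions: cohort size and subtype mix,
#' sample purity (a fraction of samples are pure single-subtype, the rest
#' two-way mixtures with a fixed mixing fraction), biological noise in log2
#' units, multiplicative lane-level technical factors, and panel composition
#' (marker genes per subtype, uninformative noise genes, housekeeping,
#' positive/negative controls).
#'
#' Defaults emulate the assay's data model: five equally likely subtypes,
#' 8 marker genes per subtype with a +2 log2 elevation, 10 housekeeping
#' genes, the platform-standard 4-fold positive-control ladder, lane factors
#' log-uniform in \[0.5, 2\], 80% pure samples with two-way mixtures at 0.7,
#' and log2-scale Gaussian noise of 0.25.
#'
#' @param n_samples Number of lanes/samples.
#' @param subtype_proportions Named simplex over [crca_subtypes()].
#' @param pure_fraction Fraction of samples that are pure single-subtype.
#' @param mixing_fraction Mixing fraction pi of the dominant subtype in
#'   two-way mixture samples.
#' @param noise_sd Gene-level Gaussian noise SD, log2 units.
#' @param lane_factor_range Multiplicative lane factor range (log-uniform).
#' @param n_marker_genes Marker genes per subtype.
#' @param n_noise_genes Uninformative endogenous genes.
#' @param n_housekeeping Housekeeping probes (default 10).
#' @param baseline_log2,marker_delta Baseline log2 abundance and marker
#'   elevation.
#' @param hk_log2_mean Housekeeping log2 abundance (constant across samples).
#' @param pos_scale Counts of the top positive-control rung at lane factor 1;
#'   lower rungs scale down the 4-fold ladder.
#' @param n_negative Negative-control probes.
#' @param neg_lambda Poisson mean of negative-control background counts.
#' @param count_model `"lognormal"` (rounded, default) or `"nb"` (negative
#'   binomial with dispersion `nb_size`).
#' @param nb_size Negative-binomial size parameter when `count_model = "nb"`.
#' @param seed Integer seed; mandatory, every draw flows from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 60,
                              subtype_proportions = stats::setNames(rep(0.2, 5), crca_subtypes()),
                              pure_fraction = 0.8,
                              mixing_fraction = 0.7,
                              noise_sd = 0.25,
                              lane_factor_range = c(0.5, 2),
                              n_marker_genes = 8,
                              n_noise_genes = 10,
                              n_housekeeping = 10,
                              baseline_log2 = 8,
                              marker_delta = 2,
                              hk_log2_mean = 10,
                              pos_scale = 8192,
                              n_negative = 8,
                              neg_lambda = 2,
                              count_model = c("lognormal", "nb"),
                              nb_size = 20,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory in simulation_config()", call. = FALSE)
  count_model <- match.arg(count_model)
  stopifnot(n_samples >= 1, n_housekeeping >= 1, n_negative >= 2,
            noise_sd >= 0, pure_fraction >= 0, pure_fraction <= 1,
            mixing_fraction > 0.5, mixing_fraction <= 1,
            length(lane_factor_range) == 2, all(lane_factor_range > 0),
            lane_factor_range[1] <= lane_factor_range[2])
  if (abs(sum(subtype_proportions) - 1) > 1e-8) {
    stop("subtype_proportions must sum to 1", call. = FALSE)
  }
  if (is.null(names(subtype_proportions))) {
    names(subtype_proportions) <- crca_subtypes()[seq_along(subtype_proportions)]
  }
  structure(as.list(environment()), class = "simulation_config")
}

subtype_abbrev <- function(s) {
  ab <- c("goblet-like" = "GOB", "enterocyte" = "ENT", "stem-like" = "STM",
          "inflammatory" = "INF", "TA" = "TA")[s]
  unname(ifelse(is.na(ab), toupper(substr(s, 1, 3)), ab))
}

#' Build block-structured subtype centroids
#'
#' Each subtype gets `n_marker_genes` marker genes elevated by
#' `marker_delta` log2 units in its own column and at baseline elsewhere;
#' noise genes are flat across all subtypes.
#'
#' @param config A [simulation_config()].
#' @return A centroid tibble (`gene` + one column per subtype).
#' @export
make_centroids <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  subtypes <- names(config$subtype_proportions)
  marker_genes <- unlist(lapply(subtypes, function(s) {
    sprintf("%s_%02d", subtype_abbrev(s), seq_len(config$n_marker_genes))
  }))
  noise_genes <- if (config$n_noise_genes > 0)
    sprintf("NSE_%02d", seq_len(config$n_noise_genes)) else character()
  genes <- c(marker_genes, noise_genes)
  m <- matrix(config$baseline_log2, nrow = length(genes), ncol = length(subtypes),
              dimnames = list(genes, subtypes))
  for (j in seq_along(subtypes)) {
    if (config$n_marker_genes > 0) {
      idx <- (j - 1) * config$n_marker_genes + seq_len(config$n_marker_genes)
      m[idx, j] <- config$baseline_log2 + config$marker_delta
    }
  }
  matrix_to_expr(m)
}

#' Simulate an nCounter experiment with planted truth
#'
#' Generates per-sample raw counts from centroid-structured log2 means:
#' every sample is a pure subtype or a two-way centroid mixture, gene-level
#' Gaussian noise is added in log2 space, and counts are
#' `round(lane_factor * 2^mean)` (or negative-binomial draws around that
#' mean). Housekeeping probes are constant in log-mean (stable reference
#' genes by construction) and carry only the lane factor; positive controls
#' follow the standard 4-fold concentration ladder scaled by the lane
#' factor; negative controls are small Poisson background. Identical
#' configurations (same seed) regenerate the data bitwise.
#'
#' @param config A [simulation_config()].
#' @param centroids Optional centroid tibble; defaults to
#'   [make_centroids()] on `config`.
#' @return Object of class `nano_sim`: list with `raw` (a `nano_counts`
#'   object ready for [qc_lanes()]/[normalize_counts()]), `truth` (tibble
#'   `sample_id`, `subtype`, `subtype2`, `mixing_fraction`, `lane_factor`),
#'   `centroids`, `panel`, and `config`.
#' @export
simulate_counts <- function(config, centroids = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  centroids <- centroids %||% make_centroids(config)
  cm <- centroids_to_matrix(centroids)
  subtypes <- colnames(cm)

  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  subtype <- sample(subtypes, n, replace = TRUE, prob = config$subtype_proportions)
  is_pure <- stats::runif(n) < config$pure_fraction
  subtype2 <- vapply(seq_len(n), function(i) {
    if (is_pure[i]) NA_character_ else sample(setdiff(subtypes, subtype[i]), 1)
  }, "")
  pi_mix <- ifelse(is_pure, 1, config$mixing_fraction)
  lf <- exp(stats::runif(n, log(config$lane_factor_range[1]),
                         log(config$lane_factor_range[2])))

  draw_counts <- function(mu_linear) {
    if (config$count_model == "nb") {
      stats::rnbinom(length(mu_linear), mu = mu_linear, size = config$nb_size)
    } else {
      round(mu_linear)
    }
  }

  endo <- vapply(seq_len(n), function(i) {
    mu <- pi_mix[i] * cm[, subtype[i]]
    if (!is_pure[i]) mu <- mu + (1 - pi_mix[i]) * cm[, subtype2[i]]
    if (config$noise_sd > 0) mu <- mu + stats::rnorm(nrow(cm), 0, config$noise_sd)
    draw_counts(lf[i] * 2^mu)
  }, numeric(nrow(cm)))
  endo <- matrix(endo, nrow = nrow(cm), dimnames = list(rownames(cm), ids))

  hk_genes <- sprintf("HK_%02d", seq_len(config$n_housekeeping))
  hk <- vapply(seq_len(n), function(i) {
    draw_counts(rep(lf[i] * 2^config$hk_log2_mean, config$n_housekeeping))
  }, numeric(config$n_housekeeping))
  hk <- matrix(hk, nrow = config$n_housekeeping, dimnames = list(hk_genes, ids))

  ladder <- c(128, 32, 8, 2, 0.5, 0.125)
  pos_genes <- sprintf("POS_%s(%g)", LETTERS[seq_along(ladder)], ladder)
  pos <- vapply(seq_len(n), function(i) round(lf[i] * config$pos_scale * ladder / 128),
                numeric(length(ladder)))
  pos <- matrix(pos, nrow = length(ladder), dimnames = list(pos_genes, ids))

  neg_genes <- sprintf("NEG_%s", LETTERS[seq_len(config$n_negative)])
  neg <- matrix(stats::rpois(config$n_negative * n, config$neg_lambda),
                nrow = config$n_negative, dimnames = list(neg_genes, ids))

  panel <- tibble::tibble(
    gene = c(rownames(cm), hk_genes, pos_genes, neg_genes),
    probe_class = c(rep("endogenous", nrow(cm)),
                    rep("housekeeping", length(hk_genes)),
                    rep("positive_control", length(pos_genes)),
                    rep("negative_control", length(neg_genes))),
    subtype = c(marker_subtype(rownames(cm), subtypes),
                rep(NA_character_, length(hk_genes) + length(pos_genes) + length(neg_genes)))
  )

  fov_count <- 280
  fov_counted <- sample(265:280, n, replace = TRUE)
  bd <- round(stats::runif(n, 0.3, 1.5), 3)
  lane_attributes <- tibble::tibble(sample_id = ids, fov_count = fov_count,
                                    fov_counted = fov_counted, binding_density = bd)

  raw <- structure(
    list(counts = validate_expr(matrix_to_expr(rbind(endo, hk)), "raw_counts"),
         controls = dplyr::bind_cols(
           tibble::tibble(code_class = c(rep("positive_control", length(pos_genes)),
                                         rep("negative_control", length(neg_genes)))),
           matrix_to_expr(rbind(pos, neg))),
         lane_attributes = lane_attributes,
         panel = panel),
    class = "nano_counts"
  )

  structure(
    list(raw = raw,
         truth = tibble::tibble(sample_id = ids, subtype = subtype,
                                subtype2 = subtype2, mixing_fraction = pi_mix,
                                lane_factor = lf),
         centroids = centroids, panel = panel, config = config),
    class = "nano_sim"
  )
}

marker_subtype <- function(genes, subtypes) {
  ab <- unname(vapply(subtypes, subtype_abbrev, ""))
  pre <- sub("_[0-9]+$", "", genes)
  subtypes[match(pre, ab)]
}

#' Write one RCC file per simulated lane
#'
#' Serializes a simulation as NanoString RCC lane files (one per sample)
#' using [write_rcc()]. File content is a pure function of the simulation,
#' so the same configuration writes bitwise-identical files.
#'
#' @param sim A `nano_sim` object.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, one per sample.
#' @export
write_rcc_files <- function(sim, dir) {
  stopifnot(inherits(sim, "nano_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- sim$raw$counts
  ctl <- sim$raw$controls
  la <- sim$raw$lane_attributes
  panel <- sim$panel
  cc_label <- c(endogenous = "Endogenous", housekeeping = "Housekeeping",
                positive_control = "Positive", negative_control = "Negative")
  vapply(seq_len(nrow(la)), function(i) {
    s <- la$sample_id[i]
    genes <- c(counts$gene, ctl$gene)
    cls <- panel$probe_class[match(genes, panel$gene)]
    cs <- tibble::tibble(
      code_class = cc_label[cls],
      gene = genes,
      accession = paste0("SYN_", genes),
      count = c(counts[[s]], ctl[[s]])
    )
    lane <- structure(
      list(header = c(FileVersion = "1.7", SoftwareVersion = "4.0.0.3"),
           sample_attributes = c(ID = s, Owner = "synthetic", Date = "20260101",
                                 GeneRLF = "SYN_PANEL", SystemAPF = "n.a."),
           lane_attributes = c(ID = as.character(i),
                               FovCount = as.character(la$fov_count[i]),
                               FovCounted = as.character(la$fov_counted[i]),
                               BindingDensity = as.character(la$binding_density[i])),
           lane_numeric = c(ID = i, FovCount = la$fov_count[i],
                            FovCounted = la$fov_counted[i],
                            BindingDensity = la$binding_density[i]),
           code_summary = cs),
      class = "rcc_lane")
    write_rcc(lane, file.path(dir, paste0(s, ".RCC")))
    file.path(dir, paste0(s, ".RCC"))
  }, "")
}

#' @export
print.nano_sim <- function(x, ...) {
  cat("<nano_sim>", x$config$n_samples, "samples,",
      nrow(x$raw$counts), "endogenous+housekeeping probes, seed",
      x$config$seed, "\n")
  invisible(x)
}
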