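#' Default lane-level QC thresholds
#'
#' Platform-conventional defaults: imaging flag when the fraction of counted
#' fields of view falls below 0.75; binding-density flag outside
#' \[0.1, 2.25\] spots/um^2; linearity flag when the squared Pearson
#' correlation between log2 positive-control counts and log2 nominal
#' concentrations falls below 0.95; low-signal flag when the median
#' endogenous count is below the negative-control background.
#'
#' @param fov_min Minimum acceptable FovCounted/FovCount ratio.
#' @param binding_density_range Acceptable binding-density interval.
#' @param r2_min Minimum positive-control linearity (R^2).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(fov_min = 0.75,
                          binding_density_range = c(0.1, 2.25),
                          r2_min = 0.95) {
  list(fov_min = fov_min, binding_density_range = binding_density_range,
       r2_min = r2_min)
}

# nominal concentration parsed from probe names like "POS_A(128)"
pos_nominal <- function(gene) {
  conc <- suppressWarnings(as.numeric(sub("^.*\\(([-0-9.eE]+)\\).*$", "\\1", gene)))
  if (any(is.na(conc))) {
    # fall back to the platform-standard 4-fold ladder, assigned by rank
    ladder <- c(128, 32, 8, 2, 0.5, 0.125)
    if (length(gene) > length(ladder)) {
      stop("cannot infer nominal concentrations for positive controls: ",
           paste(gene[is.na(conc)], collapse = ", "), call. = FALSE)
    }
    conc <- ladder[seq_along(gene)]
  }
  conc
}

#' Per-lane quality control of raw nCounter counts
#'
#' Computes, for every sample: the fraction of imaged fields of view, the
#' binding density, positive-control linearity (squared Pearson correlation
#' between log2 counts and log2 nominal concentrations), and the
#' negative-control background (mean + 2 SD of negative probes). Samples
#' breaching a threshold are flagged; every flagged sample carries at least
#' one reason.
#'
#' @param counts A `nano_counts` object from [assemble_counts()] or
#'   [simulate_counts()].
#' @param thresholds A list from [qc_thresholds()].
#' @return A tibble of class `nano_qc` with one row per sample:
#'   `sample_id`, `fov_fraction`, `binding_density`, `positive_control_r2`,
#'   `background`, `median_endogenous`, `flags` (comma-joined, `""` if clean).
#' @export
qc_lanes <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "nano_counts"))
  ctl <- counts$controls
  if (is.null(ctl) || !nrow(ctl) ||
      !any(ctl$code_class == "positive_control") ||
      !any(ctl$code_class == "negative_control")) {
    stop("QC impossible: positive and negative control probes are required",
         call. = FALSE)
  }
  samples <- names(counts$counts)[-1]
  pos <- ctl[ctl$code_class == "positive_control", ]
  neg <- ctl[ctl$code_class == "negative_control", ]
  conc <- pos_nominal(pos$gene)

  endo_genes <- counts$panel$gene[counts$panel$probe_class == "endogenous"]
  endo <- counts$counts[counts$counts$gene %in% endo_genes, ]

  la <- counts$lane_attributes
  rows <- lapply(samples, function(s) {
    pv <- pos[[s]]
    nv <- neg[[s]]
    r2 <- if (stats::sd(log2(pv + 0.5)) == 0) 0 else
      stats::cor(log2(pv + 0.5), log2(conc))^2
    bg <- mean(nv) + 2 * stats::sd(nv)
    if (!is.finite(bg)) bg <- mean(nv)
    att <- la[la$sample_id == s, ]
    fov <- if (nrow(att) && is.finite(att$fov_count) && att$fov_count > 0)
      att$fov_counted / att$fov_count else NA_real_
    bd <- if (nrow(att)) att$binding_density else NA_real_
    med_endo <- stats::median(endo[[s]])

    flags <- character()
    if (is.finite(fov) && fov < thresholds$fov_min) flags <- c(flags, "imaging")
    if (is.finite(bd) && (bd < thresholds$binding_density_range[1] ||
                          bd > thresholds$binding_density_range[2]))
      flags <- c(flags, "binding_density")
    if (r2 < thresholds$r2_min) flags <- c(flags, "linearity")
    if (med_endo < bg) flags <- c(flags, "low_signal")

    tibble::tibble(sample_id = s, fov_fraction = fov, binding_density = bd,
                   positive_control_r2 = r2, background = bg,
                   median_endogenous = med_endo,
                   flags = paste(flags, collapse = ","))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nano_qc", class(out))
  out
}

#' Normalize raw nCounter counts to log2 expression
#'
#' Per sample, in order: (i) scale by a geometric-mean-anchored
#' positive-control factor, (ii) subtract the negative-control background
#' (mean + 2 SD) with a floor at zero, (iii) scale by a geometric-mean-anchored
#' housekeeping factor, (iv) take `log2(x + pseudocount)`. Anchoring means
#' each factor vector has geometric mean 1 across samples, so results do not
#' depend on a reference lane or on sample order. Housekeeping and control
#' probes are excluded from the returned endogenous matrix.
#'
#' Steps (i) and (ii) are optional; housekeeping scaling is the core of the
#' procedure and always applied. Background subtraction defaults off (frozen
#' tissue); enable it for FFPE material where degradation raises background.
#'
#' @param counts A `nano_counts` object, or a plain raw-count expression
#'   tibble (in which case control-dependent steps must be disabled).
#' @param panel Gene panel; defaults to the panel stored in `counts`.
#' @param positive_control Apply positive-control scaling (needs control
#'   probes).
#' @param background_subtract Subtract mean + 2 SD of negative controls.
#' @param pseudocount Added before log2; default 1 (zero counts are
#'   legitimate after background subtraction).
#' @return Object of class `nano_norm`: list with `expr` (log2 expression
#'   tibble over endogenous genes), `factors` (tibble `sample_id`,
#'   `positive_scale`, `housekeeping_scale`, `background`),
#'   `normalized_counts` (linear-scale normalized endogenous + housekeeping
#'   counts, for factor re-estimation), and `settings`.
#' @export
normalize_counts <- function(counts, panel = NULL,
                             positive_control = TRUE,
                             background_subtract = FALSE,
                             pseudocount = 1) {
  if (inherits(counts, "nano_counts")) {
    panel <- panel %||% counts$panel
    controls <- counts$controls
    raw <- counts$counts
  } else {
    controls <- NULL
    raw <- validate_expr(counts, "raw_counts")
    if (positive_control || background_subtract) {
      stop("control-probe steps need a `nano_counts` object with control probes",
           call. = FALSE)
    }
  }
  panel <- validate_panel(panel, require_housekeeping = TRUE)
  m <- expr_to_matrix(raw)
  samples <- colnames(m)
  cls <- panel$probe_class[match(rownames(m), panel$gene)]
  if (any(is.na(cls))) {
    stop("probes missing from panel: ",
         paste(rownames(m)[is.na(cls)], collapse = ", "), call. = FALSE)
  }
  hk <- rownames(m)[cls == "housekeeping"]
  if (!length(hk)) stop("no housekeeping probes in the count matrix", call. = FALSE)

  pos_scale <- rep(1, length(samples))
  if (positive_control) {
    pos <- controls[controls$code_class == "positive_control", ]
    if (!nrow(pos)) stop("positive-control scaling requested but no positive probes",
                         call. = FALSE)
    g <- vapply(samples, function(s) geomean(pmax(pos[[s]], 0.5)), 0)
    pos_scale <- geomean(g) / g
    m <- sweep(m, 2, pos_scale, `*`)
  }

  background <- rep(0, length(samples))
  if (background_subtract) {
    neg <- controls[controls$code_class == "negative_control", ]
    if (!nrow(neg)) stop("background subtraction requested but no negative probes",
                         call. = FALSE)
    background <- vapply(seq_along(samples), function(i) {
      nv <- neg[[samples[i]]] * pos_scale[i]
      b <- mean(nv) + 2 * stats::sd(nv)
      if (is.finite(b)) b else mean(nv)
    }, 0)
    m <- pmax(sweep(m, 2, background, `-`), 0)
  }

  hg <- vapply(samples, function(s) geomean(m[hk, s]), 0)
  if (any(hg == 0) || any(!is.finite(hg))) {
    bad <- samples[hg == 0 | !is.finite(hg)]
    stop("housekeeping geometric mean is zero/undefined for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hk_scale <- geomean(hg) / hg
  m <- sweep(m, 2, hk_scale, `*`)

  endo <- m[cls == "endogenous", , drop = FALSE]
  expr <- matrix_to_expr(log2(endo + pseudocount))

  structure(
    list(
      expr = validate_expr(expr, "log2_expression"),
      factors = tibble::tibble(sample_id = samples,
                               positive_scale = unname(pos_scale),
                               housekeeping_scale = unname(hk_scale),
                               background = unname(background)),
      normalized_counts = matrix_to_expr(m),
      settings = list(positive_control = positive_control,
                      background_subtract = background_subtract,
                      pseudocount = pseudocount)
    ),
    class = "nano_norm"
  )
}

#' @export
print.nano_norm <- function(x, ...) {
  cat("<nano_norm>", nrow(x$expr), "endogenous genes x", ncol(x$expr) - 1L,
      "samples (log2)\n")
  cat("housekeeping scale range:",
      paste(signif(range(x$factors$housekeeping_scale), 4), collapse = " - "), "\n")
  invisible(x)
}

#' @method tidy nano_norm
#' @export
tidy.nano_norm <- function(x, ...) x$factors

#' @method glance nano_norm
#' @export
glance.nano_norm <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$expr),
    n_samples = ncol(x$expr) - 1L,
    positive_control = x$settings$positive_control,
    background_subtract = x$settings$background_subtract,
    pseudocount = x$settings$pseudocount
  )
}
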