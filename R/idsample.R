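#' Estimate per-sample subtype mixture weights by support vector regression
#'
#' Fits, for each sample, a linear-kernel nu-support-vector regression of the
#' sample's expression vector on the columns of a reference centroid matrix,
#' following the CIBERSORT deconvolution convention: both the sample vector
#' and each centroid column are z-scored across the shared genes, the fit is
#' run over a nu grid and the fit with the lowest root-mean-square error
#' between fitted and observed values is kept. Negative subtype weights mean
#' the subtype is not represented in the sample: they are set to zero and the
#' surviving positive weights are renormalized to proportions. A sample whose
#' largest proportion strictly exceeds the purity threshold (70% by default)
#' is marked as representing a single subtype.
#'
#' @param expr Expression tibble (`gene` + sample columns), log2 scale.
#' @param centroids Centroid tibble (`gene` + one column per subtype).
#' @param nu Grid of nu values for the nu-SVR; lowest-RMSE fit wins.
#' @param min_overlap Minimum number of genes shared between `expr` and
#'   `centroids` (error below this).
#' @param purity_threshold Strict lower bound on the maximum proportion for a
#'   sample to count as single-subtype.
#' @param min_explained Minimum fraction of the sample's (standardized)
#'   variance the SVR fit must explain for the weights to count as a
#'   composition. Below it the sample is treated as containing no detectable
#'   subtype signal: proportions are the all-zero sentinel (the behaviour of
#'   an exact non-negative least-squares fit on such profiles), and the
#'   sample is never selected.
#' @return A tibble of class `idsample_weights`, one row per sample x
#'   subtype: `sample_id`, `subtype`, `raw_weight`, `proportion`. Per-sample
#'   fit metadata (chosen nu, RMSE, all-zero sentinel) is in
#'   `attr(, "fit")`; the threshold in `attr(, "purity_threshold")`.
#' @seealso [summarize_weights()], [select_pure_samples()]
#' @export
#' @examples
#' cen <- make_centroids(simulation_config(seed = 1))
#' expr <- cen[c("gene", "stem-like")]
#' names(expr)[2] <- "S1"
#' w <- estimate_weights(expr, cen)
#' summarize_weights(w)
estimate_weights <- function(expr, centroids, nu = c(0.25, 0.5, 0.75),
                             min_overlap = 10, purity_threshold = 0.70,
                             min_explained = 0.05) {
  expr <- validate_expr(expr)
  centroids <- validate_centroids(centroids)
  shared <- intersect(expr$gene, centroids$gene)
  if (length(shared) < min_overlap) {
    stop("only ", length(shared), " genes shared with centroids (need >= ",
         min_overlap, ")", call. = FALSE)
  }
  cm <- centroids_to_matrix(centroids)[shared, , drop = FALSE]
  em <- expr_to_matrix(expr)[shared, , drop = FALSE]
  subtypes <- colnames(cm)

  # z-score each centroid column across the shared genes
  cz <- scale(cm)
  if (any(!is.finite(cz))) {
    stop("a centroid column is constant over the shared genes", call. = FALSE)
  }
  if (qr(cz)$rank < ncol(cz)) {
    warning("centroid matrix is rank-deficient over the shared genes; ",
            "weights may not be unique")
  }

  fit_one <- function(y) {
    sdy <- stats::sd(y)
    if (sdy == 0) {
      return(list(w = rep(0, length(subtypes)), nu = NA_real_, rmse = NA_real_,
                  explained = 0))
    }
    yz <- (y - mean(y)) / sdy
    best <- NULL
    for (v in nu) {
      fit <- e1071::svm(x = cz, y = yz, type = "nu-regression",
                        kernel = "linear", nu = v, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      rmse <- sqrt(mean((stats::predict(fit, cz) - yz)^2))
      if (is.null(best) || rmse < best$rmse) best <- list(w = w, nu = v, rmse = rmse)
    }
    best$explained <- 1 - best$rmse^2 / mean(yz^2)
    best
  }

  samples <- colnames(em)
  res <- lapply(samples, function(s) fit_one(em[, s]))

  long <- purrr::map2_dfr(res, samples, function(r, s) {
    raw <- unname(r$w)
    pos <- pmax(raw, 0)
    no_signal <- all(raw <= 0) || r$explained < min_explained
    prop <- if (!no_signal && sum(pos) > 0) pos / sum(pos) else rep(0, length(pos))
    tibble::tibble(sample_id = s, subtype = subtypes,
                   raw_weight = raw, proportion = prop)
  })
  fit_info <- tibble::tibble(
    sample_id = samples,
    nu = vapply(res, function(r) r$nu, 0),
    rmse = vapply(res, function(r) r$rmse, 0),
    explained = vapply(res, function(r) r$explained, 0),
    all_zero = vapply(res, function(r) all(r$w <= 0) || r$explained < min_explained, TRUE)
  )
  structure(long,
            class = c("idsample_weights", class(long)),
            fit = fit_info,
            purity_threshold = purity_threshold)
}

#' Summarize mixture weights to one row per sample
#'
#' Derives for every sample the subtype with the largest proportion, that
#' proportion, and whether the sample passes the strict purity rule
#' (`max_proportion > purity_threshold`). Ties at the maximum resolve to the
#' subtype earliest in canonical order, with a warning.
#'
#' @param weights An `idsample_weights` tibble from [estimate_weights()], or
#'   any long tibble with `sample_id`, `subtype`, `proportion` columns.
#' @param purity_threshold Defaults to the threshold stored on `weights`,
#'   else 0.70.
#' @return Tibble: `sample_id`, `max_subtype`, `max_proportion`, `selected`.
#' @export
summarize_weights <- function(weights, purity_threshold = NULL) {
  stopifnot(all(c("sample_id", "subtype", "proportion") %in% names(weights)))
  thr <- purity_threshold %||% attr(weights, "purity_threshold") %||% 0.70
  canon <- c(crca_subtypes(), setdiff(unique(weights$subtype), crca_subtypes()))
  out <- weights |>
    dplyr::mutate(.ord = match(.data$subtype, canon)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      mx <- max(d$proportion)
      at_max <- which(d$proportion == mx)
      if (length(at_max) > 1L && mx > 0) {
        warning("tie at maximum proportion for sample ", key$sample_id,
                "; assigning earliest subtype in canonical order", call. = FALSE)
      }
      pick <- at_max[which.min(d$.ord[at_max])]
      tibble::tibble(max_subtype = d$subtype[pick], max_proportion = mx)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(selected = .data$max_proportion > thr)
  # preserve input sample order
  out[match(unique(weights$sample_id), out$sample_id), ]
}

#' Select near-pure single-subtype samples
#'
#' Returns, in input order, the samples whose maximum subtype proportion
#' strictly exceeds the purity threshold. A sample at exactly the threshold
#' is not selected (the rule is strict).
#'
#' @inheritParams summarize_weights
#' @param purity_threshold Strict lower bound, default 0.70.
#' @return Character vector of selected sample ids.
#' @export
select_pure_samples <- function(weights, purity_threshold = 0.70) {
  if (!length(weights) || (is.data.frame(weights) && !nrow(weights))) return(character())
  s <- if (all(c("max_proportion", "sample_id") %in% names(weights))) {
    tibble::as_tibble(weights)
  } else {
    summarize_weights(weights, purity_threshold)
  }
  s$sample_id[s$max_proportion > purity_threshold]
}

#' @method tidy idsample_weights
#' @export
tidy.idsample_weights <- function(x, ...) {
  dplyr::left_join(tibble::as_tibble(x), attr(x, "fit"), by = "sample_id")
}

#' @method glance idsample_weights
#' @export
glance.idsample_weights <- function(x, ...) {
  s <- summarize_weights(x)
  tibble::tibble(n_samples = nrow(s),
                 n_selected = sum(s$selected),
                 purity_threshold = attr(x, "purity_threshold"),
                 mean_rmse = mean(attr(x, "fit")$rmse, na.rm = TRUE))
}
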