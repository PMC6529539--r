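#' Gene-wise median centring
#'
#' Subtracts from every gene row its median across the samples in the batch,
#' so each gene's output median is exactly zero. Centring is a cohort
#' operation: calls downstream depend on which samples are centred together,
#' and a single-sample matrix centres to all zeros (see
#' [classify_subtypes()] for the reference-median escape hatch).
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @return Tibble of the same shape, each row median-centred.
#' @export
#' @examples
#' median_center(tibble::tibble(gene = "g", a = 1, b = 2, c = 3))
median_center <- function(expr) {
  expr <- validate_expr(expr)
  m <- expr_to_matrix(expr)
  matrix_to_expr(m - apply(m, 1, stats::median))
}

#' Assign CRCA subtypes by nearest-centroid correlation
#'
#' Each sample's gene-wise median-centred profile is correlated (Pearson)
#' with every centroid column over the shared genes; the subtype with the
#' highest correlation is assigned. A sample is "undetermined" when its best
#' correlation is at or below `r_min` (default 0.15, reason
#' `low_correlation`) or when the gap between the best and second-best
#' correlations is at or below `margin_min` (default 0.06, reason
#' `low_margin`) -- both boundaries inclusive, so a sample sitting exactly on
#' a threshold is undetermined. Numerical argmax ties fall under the margin
#' rule automatically.
#'
#' @param expr Expression tibble, log2 scale.
#' @param centroids Centroid tibble.
#' @param r_min Undetermined when best r <= this.
#' @param margin_min Undetermined when (r1 - r2) <= this.
#' @param min_overlap Minimum genes shared with the centroids; below it every
#'   sample is undetermined with reason `insufficient_genes`.
#' @param auto_center Median-centre `expr` before correlating. Set `FALSE`
#'   if the matrix is already centred.
#' @param min_samples Minimum batch size for cohort centring (default 5);
#'   smaller batches need `reference_medians`.
#' @param reference_medians Optional tibble (`gene`, `median`) of frozen
#'   per-gene medians for true single-sample classification.
#' @return Tibble of class `subtype_calls`: `sample_id`, `assigned`
#'   (subtype or `"undetermined"`), `best_r`, `margin`, `reason`
#'   (`ok`, `low_correlation`, `low_margin`, `insufficient_genes`), then one
#'   correlation column `r_<subtype>` per centroid.
#' @export
classify_subtypes <- function(expr, centroids, r_min = 0.15, margin_min = 0.06,
                              min_overlap = 30, auto_center = TRUE,
                              min_samples = 5, reference_medians = NULL) {
  expr <- validate_expr(expr)
  centroids <- validate_centroids(centroids)
  samples <- names(expr)[-1]
  subtypes <- names(centroids)[-1]

  if (auto_center) {
    if (!is.null(reference_medians)) {
      stopifnot(all(c("gene", "median") %in% names(reference_medians)))
      med <- reference_medians$median[match(expr$gene, reference_medians$gene)]
      if (any(is.na(med))) {
        stop("reference medians missing for some genes", call. = FALSE)
      }
      m <- expr_to_matrix(expr) - med
      expr <- matrix_to_expr(m)
    } else {
      if (length(samples) < min_samples) {
        stop("cohort median-centring needs >= ", min_samples, " samples; ",
             "supply `reference_medians` for single-sample use", call. = FALSE)
      }
      expr <- median_center(expr)
    }
  }

  shared <- intersect(expr$gene, centroids$gene)
  rcols <- paste0("r_", subtypes)
  if (length(shared) < min_overlap) {
    out <- tibble::tibble(sample_id = samples, assigned = "undetermined",
                          best_r = NA_real_, margin = NA_real_,
                          reason = "insufficient_genes")
    out[rcols] <- NA_real_
    class(out) <- c("subtype_calls", class(out))
    return(out)
  }

  em <- expr_to_matrix(expr)[shared, , drop = FALSE]
  cm <- centroids_to_matrix(centroids)[shared, , drop = FALSE]

  rows <- lapply(samples, function(s) {
    x <- em[, s]
    if (stats::sd(x) == 0) {
      r <- rep(0, length(subtypes))
    } else {
      r <- as.numeric(stats::cor(x, cm))
    }
    call <- apply_call_rules(stats::setNames(r, subtypes), r_min, margin_min)
    row <- tibble::tibble(sample_id = s, assigned = call$assigned,
                          best_r = call$best_r, margin = call$margin,
                          reason = call$reason)
    row[rcols] <- as.list(r)
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("subtype_calls", class(out))
  out
}

#' Apply the undetermined rules to a correlation profile
#'
#' The decision rule of the nearest-centroid classifier, separated from the
#' correlation computation: given one sample's Pearson correlations against
#' every centroid, assign the argmax subtype unless the best correlation is
#' at or below `r_min` (reason `low_correlation`) or the top-two margin is at
#' or below `margin_min` (reason `low_margin`). Both comparisons are
#' inclusive: a profile exactly on a threshold is undetermined.
#'
#' @param correlations Named numeric vector, one Pearson r per subtype.
#' @param r_min,margin_min Inclusive undetermined thresholds.
#' @return List: `assigned` (subtype or `"undetermined"`), `best_r`,
#'   `margin`, `reason`.
#' @export
#' @examples
#' apply_call_rules(c(a = 0.6, b = 0.2, c = -0.1))
apply_call_rules <- function(correlations, r_min = 0.15, margin_min = 0.06) {
  stopifnot(is.numeric(correlations), length(correlations) >= 2,
            !is.null(names(correlations)))
  ord <- order(correlations, decreasing = TRUE)
  r1 <- correlations[[ord[1]]]
  margin <- r1 - correlations[[ord[2]]]
  if (r1 <= r_min) {
    list(assigned = "undetermined", best_r = r1, margin = margin,
         reason = "low_correlation")
  } else if (margin <= margin_min) {
    list(assigned = "undetermined", best_r = r1, margin = margin,
         reason = "low_margin")
  } else {
    list(assigned = names(correlations)[ord[1]], best_r = r1, margin = margin,
         reason = "ok")
  }
}

#' Per-sample subtype weights against the same centroids
#'
#' Convenience bridge between the classifier and the mixture-weight view of
#' the same samples: delegates to [estimate_weights()] with identical inputs,
#' so classifier calls and weight profiles can be tabulated side by side.
#'
#' @inheritParams classify_subtypes
#' @param ... Passed through to [estimate_weights()].
#' @return An `idsample_weights` tibble.
#' @export
classify_weighted_proxy <- function(expr, centroids, ...) {
  estimate_weights(expr, centroids, ...)
}

#' @method glance subtype_calls
#' @export
glance.subtype_calls <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_classifiable = sum(x$reason == "ok"),
    n_undetermined = sum(x$reason != "ok"),
    percent_classifiable = 100 * mean(x$reason == "ok")
  )
}
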