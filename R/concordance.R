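#' Concordance between two subtype-call sets
#'
#' Drops every sample that is undetermined in either set, then reports how
#' many of the remaining (classifiable-in-both) samples received the same
#' subtype, the agreement percentage, and a Fisher's exact test on the
#' cross-tabulation of the two call sets. The Fisher p-value is computed
#' exactly when the classifiable total is at most `exact_max` and by seeded
#' Monte-Carlo otherwise; the method used is recorded in the result. The
#' statistic is symmetric in its two arguments.
#'
#' @param calls_a,calls_b `subtype_calls` tibbles (or data frames with
#'   `sample_id` and `assigned`) over the same sample ids.
#' @param exact_max Largest classifiable n for exact Fisher computation.
#' @param mc_draws Monte-Carlo replicates beyond `exact_max`.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return Object of class `concordance_result`: `n_classifiable`,
#'   `n_agree`, `percent` (NA with `flag = "no_classifiable_samples"` when
#'   nothing survives), `fisher_p`, `fisher_method`
#'   (`"exact"`/`"monte_carlo"`/`"none"`), `table`.
#' @export
concordance <- function(calls_a, calls_b, exact_max = 200, mc_draws = 1e5,
                        seed = 1) {
  a <- normalize_calls(calls_a)
  b <- normalize_calls(calls_b)
  if (!setequal(a$sample_id, b$sample_id)) {
    stop("the two call sets must cover the same sample ids", call. = FALSE)
  }
  b <- b[match(a$sample_id, b$sample_id), ]
  keep <- a$assigned != "undetermined" & b$assigned != "undetermined"
  la <- a$assigned[keep]
  lb <- b$assigned[keep]
  n_cl <- sum(keep)
  n_agree <- sum(la == lb)

  if (n_cl == 0) {
    res <- list(n_classifiable = 0L, n_agree = 0L, percent = NA_real_,
                fisher_p = NA_real_, fisher_method = "none",
                table = table(character(), character()),
                flag = "no_classifiable_samples")
    return(structure(res, class = "concordance_result"))
  }

  lev <- sort(union(la, lb))
  tab <- table(factor(la, lev), factor(lb, lev))
  if (length(lev) < 2) {
    fp <- NA_real_; method <- "none"
  } else if (n_cl <= exact_max) {
    ft <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                   error = function(e) NULL)
    if (is.null(ft)) {
      set.seed(seed)
      ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)
      method <- "monte_carlo"
    } else method <- "exact"
    fp <- ft$p.value
  } else {
    set.seed(seed)
    fp <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)$p.value
    method <- "monte_carlo"
  }

  structure(
    list(n_classifiable = n_cl, n_agree = n_agree,
         percent = 100 * n_agree / n_cl,
         fisher_p = fp, fisher_method = method, table = tab, flag = NULL),
    class = "concordance_result"
  )
}

normalize_calls <- function(x) {
  if (!is.data.frame(x) || !all(c("sample_id", "assigned") %in% names(x))) {
    stop("calls must be a data frame with sample_id and assigned columns",
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) stop("duplicate sample ids in calls", call. = FALSE)
  tibble::as_tibble(x)[c("sample_id", "assigned")]
}

#' @export
print.concordance_result <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("<concordance_result> no classifiable samples\n")
    return(invisible(x))
  }
  cat(sprintf("<concordance_result> %.1f%% (%d/%d classifiable), Fisher p = %.3g (%s)\n",
              x$percent, x$n_agree, x$n_classifiable, x$fisher_p, x$fisher_method))
  invisible(x)
}

#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(n_classifiable = x$n_classifiable, n_agree = x$n_agree,
                 percent = x$percent, fisher_p = x$fisher_p,
                 fisher_method = x$fisher_method)
}

#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$table)) |>
    stats::setNames(c("subtype_a", "subtype_b", "n"))
}

#' Equality-of-proportions tests across classifiers
#'
#' For every subtype, tests whether the proportion of classifiable samples
#' assigned that subtype is equal across two or more classifiers
#' (chi-squared test of equal proportions; Yates continuity correction
#' applies in the two-classifier case, as in [stats::prop.test()]).
#'
#' @param calls_list A named list of two or more call sets.
#' @return Tibble: `subtype`, per-classifier counts `x_<name>`, `statistic`,
#'   `df`, `p_value`.
#' @export
proportion_tests <- function(calls_list) {
  if (!is.list(calls_list) || length(calls_list) < 2) {
    stop("need call sets from at least two classifiers", call. = FALSE)
  }
  calls_list <- lapply(calls_list, normalize_calls)
  nm <- names(calls_list) %||% paste0("classifier", seq_along(calls_list))
  nm[nm == ""] <- paste0("classifier", which(nm == ""))
  classifiable <- lapply(calls_list, function(d) d$assigned[d$assigned != "undetermined"])
  n <- vapply(classifiable, length, 0L)
  if (any(n == 0)) stop("a classifier has no classifiable samples", call. = FALSE)
  subtypes <- sort(unique(unlist(classifiable)))
  rows <- lapply(subtypes, function(s) {
    x <- vapply(classifiable, function(v) sum(v == s), 0L)
    pt <- suppressWarnings(stats::prop.test(x, n))
    out <- tibble::tibble(subtype = s)
    out[paste0("x_", nm)] <- as.list(as.integer(x))
    out$statistic <- unname(pt$statistic)
    out$df <- unname(pt$parameter)
    out$p_value <- pt$p.value
    out
  })
  dplyr::bind_rows(rows)
}

#' Subtype distribution of a call set
#'
#' Counts and percentages per assigned subtype, including the undetermined
#' category. Counts sum to the number of samples; percentages to 100.
#'
#' @param calls A call set (`sample_id`, `assigned`).
#' @return Tibble: `subtype`, `n`, `percent`.
#' @export
subtype_distribution <- function(calls) {
  calls <- normalize_calls(calls)
  if (!nrow(calls)) stop("empty call set", call. = FALSE)
  canon <- c(crca_subtypes(), "undetermined")
  lev <- c(intersect(canon, unique(calls$assigned)),
           setdiff(unique(calls$assigned), canon))
  calls |>
    dplyr::count(subtype = factor(.data$assigned, lev), .drop = FALSE) |>
    dplyr::mutate(subtype = as.character(.data$subtype),
                  percent = 100 * .data$n / nrow(calls))
}
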