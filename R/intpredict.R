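#' Misclassification error rate
#'
#' The fraction of test samples whose predicted class differs from the known
#' class: `MCR = (1/k) * sum(e_i)` with `e_i` the 0/1 misclassification
#' indicator over the `k` test samples.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return A single ratio in \[0, 1\].
#' @export
#' @examples
#' mcr(c("a", "a", "b"), c("a", "b", "b"))
mcr <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (!length(predicted)) stop("empty label vectors", call. = FALSE)
  mean(as.character(predicted) != as.character(truth))
}

# vapply over classes drops to a vector when there is a single gene; force
# the genes-by-classes matrix shape back
gene_class_matrix <- function(v, n_genes, classes) {
  matrix(v, nrow = n_genes, dimnames = list(NULL, classes))
}

align_labels <- function(expr, labels) {
  samples <- names(expr)[-1]
  if (!is.null(names(labels))) labels <- labels[samples]
  if (length(labels) != length(samples) || any(is.na(labels))) {
    stop("labels must cover every sample column", call. = FALSE)
  }
  as.character(labels)
}

# per-gene class summary pieces shared by the selectors
class_stats <- function(m, labels) {
  classes <- unique(labels)
  n <- ncol(m)
  overall <- rowMeans(m)
  means <- gene_class_matrix(
    vapply(classes, function(k) rowMeans(m[, labels == k, drop = FALSE]),
           numeric(nrow(m))),
    nrow(m), classes)
  list(classes = classes, n = n, overall = overall, means = means)
}

#' Rank genes by between-to-within group sum of squares
#'
#' For each gene, `BW = sum_k n_k (xbar_k - xbar)^2 / sum_k sum_{i in k}
#' (x_i - xbar_k)^2`. A gene constant within every class but differing
#' between classes has zero within-SS and ranks first (ratio treated as
#' infinite); a gene identical across all samples takes BW = 0 by the 0/0
#' convention and ranks last. Ties keep input gene order.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param labels Class label per sample (named or in column order).
#' @param n_genes Number of top-ranked genes to return.
#' @return Character vector of `n_genes` gene ids, best first.
#' @export
select_genes_bw <- function(expr, labels, n_genes) {
  expr <- validate_expr(expr)
  labels <- align_labels(expr, labels)
  if (length(unique(labels)) < 2L) stop("need >= 2 classes", call. = FALSE)
  m <- expr_to_matrix(expr)
  st <- class_stats(m, labels)
  between <- rowSums(gene_class_matrix(vapply(st$classes, function(k) {
    sum(labels == k) * (st$means[, k] - st$overall)^2
  }, numeric(nrow(m))), nrow(m), st$classes))
  within <- rowSums(gene_class_matrix(vapply(st$classes, function(k) {
    rowSums((m[, labels == k, drop = FALSE] - st$means[, k])^2)
  }, numeric(nrow(m))), nrow(m), st$classes))
  bw <- ifelse(within > 0, between / within,
               ifelse(between > 0, Inf, 0))
  expr$gene[order(-bw)][seq_len(min(n_genes, nrow(m)))]
}

#' Rank genes by the shrunken-centroid (PAM) statistic
#'
#' For gene `i` and class `k`, `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))`
#' with `s_i` the pooled within-class standard deviation,
#' `m_k = sqrt(1/n_k - 1/n)` and `s0` the median of the `s_i`. Genes are
#' ranked by `max_k |d_ik|`; ties keep input order.
#'
#' @inheritParams select_genes_bw
#' @return Character vector of `n_genes` gene ids, best first.
#' @export
select_genes_pam <- function(expr, labels, n_genes) {
  expr <- validate_expr(expr)
  labels <- align_labels(expr, labels)
  m <- expr_to_matrix(expr)
  score <- pam_scores(m, labels)$score
  expr$gene[order(-score)][seq_len(min(n_genes, nrow(m)))]
}

pam_scores <- function(m, labels) {
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  n <- ncol(m)
  nk <- vapply(classes, function(k) sum(labels == k), 0L)
  if (any(nk < 2L)) stop("every class needs >= 2 samples", call. = FALSE)
  overall <- rowMeans(m)
  means <- gene_class_matrix(
    vapply(classes, function(k) rowMeans(m[, labels == k, drop = FALSE]),
           numeric(nrow(m))),
    nrow(m), classes)
  within_ss <- rowSums(gene_class_matrix(vapply(classes, function(k) {
    rowSums((m[, labels == k, drop = FALSE] - means[, k])^2)
  }, numeric(nrow(m))), nrow(m), classes))
  s <- sqrt(within_ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(pmax(1 / nk - 1 / n, 0))
  d <- sweep(means - overall, 1, s + s0, `/`)
  d <- sweep(d, 2, mk, `/`)
  list(d = d, score = apply(abs(d), 1, max), s = s, s0 = s0, mk = mk,
       means = means, overall = overall, classes = classes)
}

#' Rank genes by one-vs-rest prediction strength
#'
#' A per-gene signal-to-noise reconstruction of the prediction-strength
#' criterion: `max_k |xbar_k - xbar_rest| / (s_k + s_rest)`, each class
#' against the pool of all others. (The original criterion is cited in the
#' literature without a closed form; this one-vs-rest signal-to-noise score
#' is this package's reconstruction.) Ties keep input order.
#'
#' @inheritParams select_genes_bw
#' @return Character vector of `n_genes` gene ids, best first.
#' @export
select_genes_ps <- function(expr, labels, n_genes) {
  expr <- validate_expr(expr)
  labels <- align_labels(expr, labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  m <- expr_to_matrix(expr)
  per_class <- gene_class_matrix(vapply(classes, function(k) {
    a <- m[, labels == k, drop = FALSE]
    b <- m[, labels != k, drop = FALSE]
    num <- abs(rowMeans(a) - rowMeans(b))
    den <- apply(a, 1, stats::sd) + apply(b, 1, stats::sd)
    ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  }, numeric(nrow(m))), nrow(m), classes)
  score <- apply(per_class, 1, max)
  expr$gene[order(-score)][seq_len(min(n_genes, nrow(m)))]
}

# ---- classifiers ----------------------------------------------------------

# Diagonal linear discriminant analysis from its closed form: class means,
# pooled per-gene variances, diagonal Gaussian discriminant with training
# class priors.
dlda_fit <- function(x, y) {
  classes <- sort(unique(y))
  n <- nrow(x)
  means <- gene_class_matrix(
    vapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]),
           numeric(ncol(x))),
    ncol(x), classes)
  within_ss <- rowSums(gene_class_matrix(vapply(classes, function(k) {
    xs <- x[y == k, , drop = FALSE]
    colSums((xs - matrix(means[, k], nrow(xs), ncol(xs), byrow = TRUE))^2)
  }, numeric(ncol(x))), ncol(x), classes))
  v <- within_ss / (n - length(classes))
  v <- pmax(v, 1e-12)
  list(classes = classes, means = means, var = v,
       log_prior = log(vapply(classes, function(k) mean(y == k), 0)))
}

dlda_predict <- function(fit, x) {
  scores <- vapply(seq_along(fit$classes), function(j) {
    mu <- fit$means[, j]
    -colSums((t(x) - mu)^2 / (2 * fit$var)) + fit$log_prior[j]
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

train_predict <- function(method, xtr, ytr, xte) {
  p <- ncol(xtr)
  yf <- factor(ytr)
  switch(method,
    rf = {
      fit <- randomForest::randomForest(x = xtr, y = yf, ntree = 500,
                                        mtry = max(1, floor(sqrt(p))))
      as.character(stats::predict(fit, xte))
    },
    dlda = dlda_predict(dlda_fit(xtr, ytr), xte),
    svm_linear = {
      fit <- e1071::svm(x = xtr, y = yf, kernel = "linear", cost = 1, scale = FALSE)
      as.character(stats::predict(fit, xte))
    },
    svm_radial = {
      fit <- e1071::svm(x = xtr, y = yf, kernel = "radial", cost = 1,
                        gamma = 1 / p, scale = FALSE)
      as.character(stats::predict(fit, xte))
    },
    stop("unknown classifier: ", method, call. = FALSE)
  )
}

#' Stratified Monte-Carlo train/test splits
#'
#' Draws `n_repeats` stratified random splits of the samples, keeping
#' `train_frac` of each class in the training partition. A split leaving any
#' class with fewer than 2 training samples or fewer than 1 test sample is
#' rejected and redrawn (bounded retries).
#'
#' @param labels Class label per sample.
#' @param n_repeats Number of splits.
#' @param train_frac Fraction of each class used for training.
#' @param seed Integer seed; splits are reproducible given the seed.
#' @param max_retries Redraw budget per repeat.
#' @return A list of integer vectors of training indices.
#' @export
mc_splits <- function(labels, n_repeats, train_frac = 2 / 3, seed,
                      max_retries = 100L) {
  set.seed(seed)
  labels <- as.character(labels)
  classes <- unique(labels)
  lapply(seq_len(n_repeats), function(r) {
    for (try in seq_len(max_retries)) {
      idx <- unlist(lapply(classes, function(k) {
        ik <- which(labels == k)
        sample(ik, max(2L, round(train_frac * length(ik))))
      }))
      idx <- sort(idx)
      test <- setdiff(seq_along(labels), idx)
      ok <- length(test) >= 1L &&
        all(vapply(classes, function(k) sum(labels[idx] == k) >= 2L, TRUE)) &&
        all(classes %in% labels[idx])
      if (ok) return(idx)
    }
    stop("could not draw a valid stratified split (class too small?)", call. = FALSE)
  })
}

#' Monte-Carlo cross-validated gene-panel evaluation
#'
#' The panel-reduction engine: over `n_repeats` stratified random
#' train/test splits, each gene-selection method (prediction strength, PAM
#' shrunken centroids, BW ratio) picks each candidate panel size on the
#' training partition only, each classifier (random forest, DLDA, linear and
#' radial SVM) is trained on the training partition over those genes, and the
#' misclassification error rate is recorded on the held-out test partition.
#' Per panel size, the draws from all selection x prediction method
#' combinations are pooled; the median MCR and a 95% interval on the median
#' (percentile bootstrap, 2000 resamples) summarize each size.
#'
#' Identical seeds give bitwise-identical draws.
#'
#' @param expr Expression tibble (log2), genes x samples.
#' @param labels Subtype label per sample; every class needs >= 2 samples.
#' @param sizes Candidate panel sizes (numbers of genes).
#' @param candidate_genes Genes eligible for selection (default: all genes in
#'   `expr`).
#' @param n_repeats Monte-Carlo repeats (default 50).
#' @param train_frac Training fraction per split (default 2/3, stratified).
#' @param selectors Subset of `c("ps", "pam", "bw")`.
#' @param classifiers Subset of `c("rf", "dlda", "svm_linear", "svm_radial")`.
#' @param seed Integer seed (mandatory).
#' @param n_boot Bootstrap resamples for the interval on the median.
#' @return Object of class `gene_panel_cv`: list with `draws` (tibble
#'   `rep`, `selector`, `classifier`, `panel_size`, `mcr`), `evaluations`
#'   (tibble `panel_size`, `median_mcr`, `ci_low`, `ci_high`, `n_draws`), and
#'   the run settings.
#' @export
run_gene_panel_cv <- function(expr, labels, sizes,
                              candidate_genes = NULL,
                              n_repeats = 50, train_frac = 2 / 3,
                              selectors = c("ps", "pam", "bw"),
                              classifiers = c("rf", "dlda", "svm_linear", "svm_radial"),
                              seed, n_boot = 2000) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  expr <- validate_expr(expr)
  labels <- align_labels(expr, labels)
  selectors <- match.arg(selectors, c("ps", "pam", "bw"), several.ok = TRUE)
  classifiers <- match.arg(classifiers,
                           c("rf", "dlda", "svm_linear", "svm_radial"),
                           several.ok = TRUE)
  candidate_genes <- candidate_genes %||% expr$gene
  if (any(sizes > length(candidate_genes))) {
    stop("a panel size exceeds the number of candidate genes", call. = FALSE)
  }
  cand <- expr[expr$gene %in% candidate_genes, ]
  m <- expr_to_matrix(cand)

  splits <- mc_splits(labels, n_repeats, train_frac, seed)
  select_fun <- list(ps = select_genes_ps, pam = select_genes_pam,
                     bw = select_genes_bw)

  draws <- list()
  set.seed(seed + 1L)  # classifier randomness (RF) flows from here
  for (r in seq_len(n_repeats)) {
    tr <- splits[[r]]
    te <- setdiff(seq_along(labels), tr)
    expr_tr <- dplyr::bind_cols(cand["gene"], cand[-1][tr])
    for (sel in selectors) {
      ranked <- select_fun[[sel]](expr_tr, labels[tr], max(sizes))
      for (sz in sizes) {
        genes <- ranked[seq_len(sz)]
        xtr <- t(m[genes, tr, drop = FALSE])
        xte <- t(m[genes, te, drop = FALSE])
        for (clf in classifiers) {
          pred <- train_predict(clf, xtr, labels[tr], xte)
          draws[[length(draws) + 1L]] <- tibble::tibble(
            rep = r, selector = sel, classifier = clf,
            panel_size = sz, mcr = mcr(pred, labels[te]))
        }
      }
    }
  }
  draws <- dplyr::bind_rows(draws)

  set.seed(seed + 2L)
  evaluations <- draws |>
    dplyr::group_by(.data$panel_size) |>
    dplyr::summarise(
      median_mcr = stats::median(.data$mcr),
      ci_low = boot_median_ci(.data$mcr, n_boot)[1],
      ci_high = boot_median_ci(.data$mcr, n_boot)[2],
      n_draws = dplyr::n(),
      .groups = "drop"
    )

  structure(
    list(draws = draws, evaluations = evaluations,
         settings = list(sizes = sort(sizes), n_repeats = n_repeats,
                         train_frac = train_frac, selectors = selectors,
                         classifiers = classifiers, seed = seed,
                         candidate_genes = candidate_genes)),
    class = "gene_panel_cv"
  )
}

boot_median_ci <- function(x, n_boot = 2000, level = 0.95) {
  meds <- vapply(seq_len(n_boot),
                 function(i) stats::median(sample(x, replace = TRUE)), 0)
  a <- (1 - level) / 2
  unname(stats::quantile(meds, c(a, 1 - a)))
}

#' @export
print.gene_panel_cv <- function(x, ...) {
  cat("<gene_panel_cv>", x$settings$n_repeats, "repeats,",
      length(x$settings$selectors), "selectors x",
      length(x$settings$classifiers), "classifiers\n")
  print(x$evaluations)
  invisible(x)
}

#' @method tidy gene_panel_cv
#' @export
tidy.gene_panel_cv <- function(x, ...) x$evaluations

#' @method glance gene_panel_cv
#' @export
glance.gene_panel_cv <- function(x, ...) {
  best <- x$evaluations[which.min(x$evaluations$median_mcr), ]
  best <- x$evaluations[x$evaluations$median_mcr == best$median_mcr, ]
  best <- best[which.min(best$panel_size), ]
  tibble::tibble(best_size = best$panel_size, best_median_mcr = best$median_mcr,
                 n_repeats = x$settings$n_repeats, n_draws = nrow(x$draws))
}

#' Choose the panel with the lowest median MCR
#'
#' Picks the candidate size whose pooled median misclassification error is
#' lowest (ties resolve to the smaller panel), then re-runs the
#' best-performing selection method at that size on the full data set to name
#' the genes. The best method is the selector with the lowest median MCR
#' among its own draws at the chosen size (ties resolve in selector order).
#'
#' @param cv A `gene_panel_cv` object.
#' @param expr,labels The full data the evaluation was run on.
#' @return List of class `panel_choice`: `panel_size`, `selector`, `genes`,
#'   `median_mcr`.
#' @export
choose_panel <- function(cv, expr, labels) {
  stopifnot(inherits(cv, "gene_panel_cv"))
  ev <- cv$evaluations
  best_m <- min(ev$median_mcr)
  size <- min(ev$panel_size[ev$median_mcr == best_m])

  by_sel <- cv$draws |>
    dplyr::filter(.data$panel_size == size) |>
    dplyr::group_by(.data$selector) |>
    dplyr::summarise(med = stats::median(.data$mcr), .groups = "drop")
  by_sel <- by_sel[match(cv$settings$selectors, by_sel$selector), ]
  by_sel <- by_sel[!is.na(by_sel$selector), ]
  sel <- by_sel$selector[which.min(by_sel$med)]

  cand <- expr[expr$gene %in% cv$settings$candidate_genes, ]
  select_fun <- list(ps = select_genes_ps, pam = select_genes_pam,
                     bw = select_genes_bw)
  genes <- select_fun[[sel]](cand, labels, size)
  structure(list(panel_size = size, selector = sel, genes = genes,
                 median_mcr = best_m),
            class = "panel_choice")
}

#' @export
print.panel_choice <- function(x, ...) {
  cat("<panel_choice>", x$panel_size, "genes via", x$selector,
      "(median MCR", signif(x$median_mcr, 3), ")\n")
  cat(paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Derive per-subtype reference centroids (PAM methodology)
#'
#' Class centroids over the given genes with optional soft-threshold
#' shrinkage toward the overall mean: the standardized deviation `d_ik` is
#' shrunk by `delta` (`sign(d) * max(|d| - delta, 0)`) and the centroid
#' reconstructed as `xbar_i + m_k (s_i + s0) d'_ik`. With the default
#' `delta = 0` the centroids are simply the class means on the input scale.
#'
#' @param expr Expression tibble (log2).
#' @param labels Subtype per sample.
#' @param genes Genes to include (default: all).
#' @param delta Shrinkage threshold (>= 0).
#' @return A centroid tibble (`gene` + one column per subtype), subtype
#'   columns in canonical order where applicable.
#' @export
derive_centroids <- function(expr, labels, genes = NULL, delta = 0) {
  expr <- validate_expr(expr)
  labels <- align_labels(expr, labels)
  if (!is.null(genes)) {
    missing <- setdiff(genes, expr$gene)
    if (length(missing)) stop("genes not in matrix: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    expr <- expr[match(genes, expr$gene), ]
  }
  m <- expr_to_matrix(expr)
  ps <- pam_scores(m, labels)
  d_shrunk <- sign(ps$d) * pmax(abs(ps$d) - delta, 0)
  cen <- ps$overall + sweep(sweep(d_shrunk, 1, ps$s + ps$s0, `*`), 2, ps$mk, `*`)
  colnames(cen) <- ps$classes
  canon <- intersect(crca_subtypes(), ps$classes)
  ord <- c(canon, setdiff(ps$classes, canon))
  rownames(cen) <- rownames(m)
  matrix_to_expr(cen[, ord, drop = FALSE])
}
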