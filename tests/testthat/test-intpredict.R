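# small labelled dataset builders -------------------------------------------

separable_data <- function(n_per_class = 6, classes = crca_subtypes()[1:3],
                           n_marker = 2, n_noise = 3, delta = 5, sd = 0.2,
                           seed = 1) {
  set.seed(seed)
  k <- length(classes)
  g <- k * n_marker + n_noise
  n <- k * n_per_class
  labels <- rep(classes, each = n_per_class)
  m <- matrix(rnorm(g * n, 0, sd), g, n)
  for (j in seq_len(k)) {
    rows <- (j - 1) * n_marker + seq_len(n_marker)
    m[rows, labels == classes[j]] <- m[rows, labels == classes[j]] + delta
  }
  rownames(m) <- c(sprintf("MK_%s_%d", rep(seq_len(k), each = n_marker),
                           rep(seq_len(n_marker), k)),
                   sprintf("NSE_%d", seq_len(n_noise)))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  list(expr = as_expr(m), labels = stats::setNames(labels, colnames(m)))
}

test_that("mcr is the fraction of misclassified test samples", {
  expect_equal(mcr(rep("a", 10), rep("a", 10)), 0)
  expect_equal(mcr(rep("a", 4), rep("b", 4)), 1)
  expect_equal(mcr(c("a", "a", "b", "b", "a", "a", "a", "a"),
                   c("b", "b", "b", "b", "a", "a", "a", "a")), 0.25)
  expect_error(mcr(c("a", "b"), "a"), "equal length")
})

test_that("BW ranking matches a direct sum-of-squares oracle and its conventions", {
  # toy 2-class set: class means 0 and 2, within-class offsets {-1, +1}
  m <- rbind(toy = c(-1, 1, 1, 3),
             flat = c(5, 5, 5, 5),
             sep = c(0, 0, 2, 2))
  colnames(m) <- sprintf("s%d", 1:4)
  labels <- c("x", "x", "y", "y")
  # oracle by brute-force summation over the 4 values of gene "toy"
  xbar <- mean(m["toy", ]); xk <- c(mean(m["toy", 1:2]), mean(m["toy", 3:4]))
  between <- 2 * (xk[1] - xbar)^2 + 2 * (xk[2] - xbar)^2
  within <- sum((m["toy", 1:2] - xk[1])^2) + sum((m["toy", 3:4] - xk[2])^2)
  expect_equal(between, 4)
  expect_equal(within, 4)
  expect_equal(between / within, 1.0)

  ranked <- select_genes_bw(as_expr(m), labels, 3)
  # "sep" is constant within classes, different between -> infinite ratio, first;
  # "flat" is constant everywhere -> 0 by convention, last
  expect_equal(ranked, c("sep", "toy", "flat"))
})

test_that("PAM and PS rank a strongly informative gene first", {
  set.seed(31)
  n <- 24
  labels <- rep(c("a", "b"), each = n / 2)
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("s%d", 1:n)))
  m[7, labels == "b"] <- m[7, labels == "b"] + 5  # 5-sigma effect
  expr <- as_expr(m)
  expect_equal(select_genes_pam(expr, labels, 1), "G07")
  expect_equal(select_genes_ps(expr, labels, 1), "G07")

  # duplicated gene -> adjacent ranks, tie broken by input order
  m2 <- rbind(m, G07b = m[7, ])
  r <- select_genes_pam(as_expr(m2), labels, 2)
  expect_equal(r, c("G07", "G07b"))

  # all-noise data still returns a valid ranking of the requested length
  expect_length(select_genes_ps(as_expr(m[-7, ]), labels, 5), 5)
})

test_that("the CV engine honours the draw-cardinality contract and reproducibility", {
  d <- separable_data(seed = 32)
  cv <- run_gene_panel_cv(d$expr, d$labels, sizes = 6, n_repeats = 1,
                          selectors = "bw", seed = 99)
  expect_equal(nrow(cv$draws), 4L)  # one per classifier
  expect_setequal(cv$draws$classifier, c("rf", "dlda", "svm_linear", "svm_radial"))

  cv2 <- run_gene_panel_cv(d$expr, d$labels, sizes = 6, n_repeats = 1,
                           selectors = "bw", seed = 99)
  expect_identical(cv$draws, cv2$draws)
  expect_true(all(cv$draws$mcr >= 0 & cv$draws$mcr <= 1))
})

test_that("perfectly separable data yields zero median MCR at sufficient sizes", {
  d <- separable_data(n_per_class = 8, sd = 0, seed = 33)
  cv <- run_gene_panel_cv(d$expr, d$labels, sizes = c(6, 8), n_repeats = 5,
                          seed = 7)
  expect_equal(cv$evaluations$median_mcr, c(0, 0))
  expect_true(all(cv$evaluations$ci_low <= cv$evaluations$median_mcr))
  expect_true(all(cv$evaluations$ci_high >= cv$evaluations$median_mcr))
})

test_that("gene selection sees only the training partition (canary check)", {
  set.seed(34)
  classes <- c("a", "b", "c")
  n <- 36
  labels <- stats::setNames(rep(classes, each = n / 3), sprintf("S%03d", 1:n))
  m <- matrix(rnorm(10 * n), 10, n,
              dimnames = list(sprintf("G%02d", 1:10), names(labels)))
  # reconstruct the single split the engine will use, then plant a canary
  # gene that separates classes perfectly on the TEST partition only
  tr <- mc_splits(labels, 1, seed = 55)[[1]]
  te <- setdiff(seq_len(n), tr)
  canary <- rnorm(n)
  canary[te] <- match(labels[te], classes) * 10
  m2 <- rbind(m, CANARY = canary)
  cv <- run_gene_panel_cv(as_expr(m2), labels, sizes = 1, n_repeats = 1,
                          seed = 55)
  # with leakage the canary would be selected and drive MCR to ~0;
  # without it, errors stay at chance level for 3 classes
  expect_gt(median(cv$draws$mcr), 0.4)
})

test_that("choose_panel takes the lowest median MCR and breaks ties downward", {
  d <- separable_data(seed = 36)
  fake <- structure(list(
    draws = tibble::tibble(
      rep = 1, selector = "bw",
      classifier = "dlda",
      panel_size = rep(c(2, 4, 6), each = 2),
      mcr = c(0.05, 0.05, 0.01, 0.01, 0.01, 0.01)),
    evaluations = tibble::tibble(panel_size = c(2, 4, 6),
                                 median_mcr = c(0.05, 0.01, 0.01),
                                 ci_low = 0, ci_high = 0.1, n_draws = 2),
    settings = list(selectors = "bw", candidate_genes = d$expr$gene)),
    class = "gene_panel_cv")
  choice <- choose_panel(fake, d$expr, d$labels)
  expect_equal(choice$panel_size, 4)
  expect_length(choice$genes, 4)
  expect_true(all(choice$genes %in% d$expr$gene))

  # single candidate size is returned unconditionally
  fake$evaluations <- fake$evaluations[1, ]
  fake$draws <- fake$draws[fake$draws$panel_size == 2, ]
  expect_equal(choose_panel(fake, d$expr, d$labels)$panel_size, 2)

  # strictly decreasing medians -> largest size
  fake2 <- fake
  fake2$evaluations <- tibble::tibble(panel_size = c(2, 4, 6),
                                      median_mcr = c(0.3, 0.2, 0.1),
                                      ci_low = 0, ci_high = 1, n_draws = 2)
  fake2$draws <- tibble::tibble(rep = 1, selector = "bw", classifier = "dlda",
                                panel_size = c(2, 4, 6), mcr = c(0.3, 0.2, 0.1))
  expect_equal(choose_panel(fake2, d$expr, d$labels)$panel_size, 6)
})

test_that("derived centroids are class means at zero shrinkage", {
  m <- rbind(g1 = c(0.8, 1.2, 2.8, 3.2),
             g2 = c(5, 5, 7, 7))
  colnames(m) <- sprintf("s%d", 1:4)
  labels <- c("x", "x", "y", "y")
  cen <- derive_centroids(as_expr(m), labels)
  expect_equal(cen$x, c(1, 5))
  expect_equal(cen$y, c(3, 7))

  # shrinkage large enough to kill every d-statistic -> overall means
  cen2 <- derive_centroids(as_expr(m), labels, delta = 1e6)
  expect_equal(cen2$x, rowMeans(m), ignore_attr = TRUE)
  expect_equal(cen2$x, cen2$y)
})

test_that("derived centroids recover planted class means within 3 SE", {
  set.seed(37)
  classes <- c("a", "b")
  n_per <- 40; sd0 <- 1
  mu <- c(a = 2, b = 5)
  vals <- c(rnorm(n_per, mu["a"], sd0), rnorm(n_per, mu["b"], sd0))
  m <- rbind(gene1 = vals, gene2 = rnorm(2 * n_per))
  colnames(m) <- sprintf("s%d", seq_len(2 * n_per))
  labels <- rep(classes, each = n_per)
  cen <- derive_centroids(as_expr(m), labels)
  se <- sd0 / sqrt(n_per)
  expect_lt(abs(cen$a[1] - mu["a"]), 3 * se)
  expect_lt(abs(cen$b[1] - mu["b"]), 3 * se)
})

test_that("stratified splits keep every class trained and are seed-stable", {
  labels <- rep(crca_subtypes(), times = c(4, 6, 8, 3, 9))
  sp <- mc_splits(labels, 10, seed = 5)
  for (tr in sp) {
    expect_true(all(table(labels[tr]) >= 2))
    expect_gt(length(setdiff(seq_along(labels), tr)), 0)
  }
  expect_identical(sp, mc_splits(labels, 10, seed = 5))
})
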