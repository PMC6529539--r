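# brute-force Pearson + rules oracle, written from the definitional formula
oracle_classify <- function(m, cm, r_min = 0.15, margin_min = 0.06) {
  pearson <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  rows <- lapply(seq_len(ncol(m)), function(i) {
    x <- m[, i]
    r <- unname(apply(cm, 2, pearson, x = x))
    ord <- order(r, decreasing = TRUE)
    r1 <- r[ord[1]]; margin <- r1 - r[ord[2]]
    assigned <- if (r1 <= r_min || margin <= margin_min) "undetermined"
                else colnames(cm)[ord[1]]
    list(assigned = assigned, r1 = r1, margin = margin)
  })
  list(assigned = vapply(rows, `[[`, "", "assigned"),
       r1 = vapply(rows, `[[`, 0, "r1"),
       margin = vapply(rows, `[[`, 0, "margin"))
}

test_that("median centring zeroes every row median and is idempotent", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 10, 40))
  colnames(m) <- sprintf("s%d", 1:3)
  centred <- median_center(as_expr(m))
  expect_equal(centred$s1, c(-1, 0))
  expect_equal(unname(expr_mat(centred)["a", ]), c(-1, 0, 1))
  expect_equal(apply(expr_mat(centred), 1, median), c(a = 0, b = 0))
  expect_equal(median_center(centred), centred)

  # single-sample matrix centres to all zeros: the documented hazard
  one <- as_expr(matrix(c(3, 7), 2, 1, dimnames = list(c("a", "b"), "s")))
  expect_equal(unname(as.matrix(median_center(one)[-1])), matrix(0, 2, 1))
})

test_that("classify matches the brute-force correlation oracle", {
  cfg <- simulation_config(seed = 41)
  cen <- make_centroids(cfg)
  cm <- expr_mat(cen)
  set.seed(41)
  n <- 50
  m <- sapply(seq_len(n), function(i) {
    s <- sample(colnames(cm), 1)
    0.8 * cm[, s] + rnorm(nrow(cm), 0, 1.5)
  })
  dimnames(m) <- list(cen$gene, sprintf("S%03d", seq_len(n)))
  calls <- classify_subtypes(as_expr(m), cen)
  oc <- oracle_classify(expr_mat(median_center(as_expr(m))), cm)
  expect_equal(calls$assigned, oc$assigned)
  expect_equal(calls$best_r, oc$r1, tolerance = 1e-12)
  expect_equal(calls$margin, oc$margin, tolerance = 1e-12)
  expect_true(all(calls$margin >= 0))
})

test_that("a centred centroid column is called with r = 1 and reason ok", {
  cfg <- simulation_config(seed = 42)
  cen <- make_centroids(cfg)
  cm <- expr_mat(cen)
  m <- cm[, rep("enterocyte", 6)] + matrix(rnorm(nrow(cm) * 6, 0, 1e-9), ncol = 6)
  m[, 6] <- cm[, "stem-like"]  # break the degenerate all-equal cohort
  colnames(m) <- sprintf("S%d", 1:6)
  calls <- classify_subtypes(as_expr(m), cen, auto_center = FALSE)
  expect_equal(calls$assigned[1:5], rep("enterocyte", 5))
  expect_equal(calls$best_r[1:5], rep(1, 5), tolerance = 1e-6)
  expect_true(all(calls$reason[1:5] == "ok"))
})

test_that("the midpoint of two centroids is undetermined by margin", {
  # the block-design centroids are symmetric: the 50/50 mixture of two
  # columns correlates identically with both parents
  cen <- make_centroids(simulation_config(seed = 40))
  cm <- expr_mat(cen)
  mid <- (cm[, "enterocyte"] + cm[, "TA"]) / 2
  e <- tibble::tibble(gene = cen$gene, M = mid)
  calls <- classify_subtypes(e, cen, auto_center = FALSE)
  expect_equal(calls$r_enterocyte, calls$r_TA, tolerance = 1e-12)
  expect_gt(calls$best_r, 0.15)
  expect_equal(calls$assigned, "undetermined")
  expect_equal(calls$reason, "low_margin")
  expect_lt(calls$margin, 1e-12)
})

test_that("pure noise far from every centroid is undetermined by correlation", {
  cfg <- simulation_config(seed = 43)
  cen <- make_centroids(cfg)
  cm <- scale(expr_mat(cen))
  set.seed(43)
  found <- 0L
  for (i in 1:20) {
    y <- rnorm(nrow(cm))
    Q <- qr.Q(qr(cbind(1, cm)))
    yo <- as.numeric(y - Q %*% crossprod(Q, y))
    e <- tibble::tibble(gene = cen$gene, N = yo)
    calls <- classify_subtypes(e, cen, auto_center = FALSE)
    expect_true(all(abs(calls[paste0("r_", crca_subtypes())]) < 0.05))
    expect_equal(calls$reason, "low_correlation")
    found <- found + 1L
  }
  expect_equal(found, 20L)
})

test_that("threshold boundaries are inclusive exactly as the rules state", {
  # correlation boundary: best r exactly at 0.15 is undetermined, 0.151 is ok
  r <- c(goblet = 0.15, enterocyte = 0.05, stem = -0.2)
  expect_equal(apply_call_rules(r)$reason, "low_correlation")
  r["goblet"] <- 0.151
  expect_equal(apply_call_rules(r)$reason, "ok")

  # margin boundary: (r2 + 0.06) - r2 is exactly 0.06 in double arithmetic here
  r2 <- 0.2
  expect_identical((r2 + 0.06) - r2, 0.06)
  rm_ <- c(a = r2 + 0.06, b = r2, c = 0)
  out <- apply_call_rules(rm_)
  expect_equal(out$margin, 0.06)
  expect_equal(out$reason, "low_margin")
  rm_["a"] <- r2 + 0.061
  expect_equal(apply_call_rules(rm_)$reason, "ok")
})

test_that("calls are invariant to per-sample affine transforms after centring", {
  cfg <- simulation_config(seed = 44)
  cen <- make_centroids(cfg)
  cm <- expr_mat(cen)
  set.seed(44)
  m <- sapply(1:8, function(i) cm[, sample(colnames(cm), 1)] + rnorm(nrow(cm), 0, 0.4))
  dimnames(m) <- list(cen$gene, sprintf("S%d", 1:8))
  centred <- median_center(as_expr(m))
  base <- classify_subtypes(centred, cen, auto_center = FALSE)
  mm <- expr_mat(centred)
  set.seed(45)
  a <- runif(8, 0.2, 5); b <- rnorm(8, 0, 10)
  trans <- sweep(sweep(mm, 2, a, `*`), 2, b, `+`)
  dimnames(trans) <- dimnames(mm)
  shifted <- classify_subtypes(as_expr(trans), cen, auto_center = FALSE)
  expect_equal(shifted$assigned, base$assigned)
  expect_equal(shifted$best_r, base$best_r, tolerance = 1e-12)
})

test_that("small batches need a reference median; insufficient overlap is flagged", {
  cfg <- simulation_config(seed = 46)
  cen <- make_centroids(cfg)
  cm <- expr_mat(cen)
  one <- tibble::tibble(gene = cen$gene, S1 = cm[, "TA"] + rnorm(nrow(cm), 0, 0.1))
  expect_error(classify_subtypes(one, cen), "reference_medians")

  ref <- tibble::tibble(gene = cen$gene, median = rowMeans(cm))
  calls <- classify_subtypes(one, cen, reference_medians = ref)
  expect_equal(calls$assigned, "TA")

  few <- one[1:10, ]
  calls2 <- classify_subtypes(few, cen, reference_medians = ref[1:10, ])
  expect_equal(calls2$reason, "insufficient_genes")
  expect_equal(calls2$assigned, "undetermined")
})

test_that("a zero-variance sample records zero correlations and low_correlation", {
  cfg <- simulation_config(seed = 47)
  cen <- make_centroids(cfg)
  m <- matrix(rnorm(nrow(cen) * 5), nrow(cen), 5,
              dimnames = list(cen$gene, sprintf("S%d", 1:5)))
  m[, 3] <- 4
  calls <- classify_subtypes(as_expr(m), cen, auto_center = FALSE)
  expect_equal(calls$reason[3], "low_correlation")
  expect_equal(unname(unlist(calls[3, paste0("r_", crca_subtypes())])), rep(0, 5))
})
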