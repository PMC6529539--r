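test_that("QC computes linearity, background and imaging metrics as defined", {
  sim <- default_sim(seed = 11, n_samples = 4)
  counts <- sim$raw

  # positive controls exactly proportional to the ladder -> r2 = 1, no flag
  qc <- qc_lanes(counts)
  expect_true(all(qc$positive_control_r2 > 0.99))
  expect_false(any(grepl("linearity", qc$flags)))

  # all-zero negatives -> background 0
  zero_neg <- counts
  neg_rows <- zero_neg$controls$code_class == "negative_control"
  for (s in names(zero_neg$counts)[-1]) zero_neg$controls[[s]][neg_rows] <- 0
  expect_equal(qc_lanes(zero_neg)$background, rep(0, 4))

  # FovCounted = FovCount/2 with threshold 0.75 -> imaging flag
  half <- counts
  half$lane_attributes$fov_counted[1] <- half$lane_attributes$fov_count[1] / 2
  expect_match(qc_lanes(half)$flags[1], "imaging")
  expect_false(grepl("imaging", qc_lanes(half)$flags[2]))
})

test_that("QC without control probes is an explicit error", {
  sim <- default_sim(seed = 11, n_samples = 4)
  counts <- sim$raw
  counts$controls <- counts$controls[counts$controls$code_class == "negative_control", ]
  expect_error(qc_lanes(counts), "control")
})

test_that("identical lanes get unit factors; a global lane factor is removed", {
  sim <- default_sim(seed = 12, n_samples = 6, noise_sd = 0,
                     lane_factor_range = c(1, 1), pure_fraction = 1)
  counts <- sim$raw
  # duplicate lane 1 into lane 2
  for (tbl in c("counts", "controls")) {
    counts[[tbl]][[counts$lane_attributes$sample_id[2]]] <-
      counts[[tbl]][[counts$lane_attributes$sample_id[1]]]
  }
  norm <- normalize_counts(counts)
  s1 <- counts$lane_attributes$sample_id[1]
  s2 <- counts$lane_attributes$sample_id[2]
  expect_equal(norm$expr[[s1]], norm$expr[[s2]])

  # lane 3 = 2x lane 1 in every probe -> equal after housekeeping scaling
  s3 <- counts$lane_attributes$sample_id[3]
  counts$counts[[s3]] <- 2 * counts$counts[[s1]]
  counts$controls[[s3]] <- 2 * counts$controls[[s1]]
  norm2 <- normalize_counts(counts, positive_control = FALSE)
  expect_equal(norm2$expr[[s3]], norm2$expr[[s1]], tolerance = 1e-12)
})

test_that("planted lane factors are recovered by housekeeping geometric means", {
  sim <- default_sim(seed = 13, n_samples = 24, lane_factor_range = c(0.5, 2))
  norm <- normalize_counts(sim$raw, positive_control = FALSE)
  truth <- sim$truth$lane_factor
  truth_anchored <- truth / exp(mean(log(truth)))
  recovered <- 1 / norm$factors$housekeeping_scale
  expect_lt(max(abs(recovered / truth_anchored - 1)), 0.02)
})

test_that("factor estimation is idempotent on normalized counts", {
  sim <- default_sim(seed = 14, n_samples = 8)
  norm <- normalize_counts(sim$raw)
  renorm <- normalize_counts(norm$normalized_counts, panel = sim$panel,
                             positive_control = FALSE)
  expect_equal(renorm$factors$housekeeping_scale, rep(1, 8), tolerance = 1e-9)
})

test_that("normalized output contains exactly the endogenous genes", {
  sim <- default_sim(seed = 15, n_samples = 6)
  norm <- normalize_counts(sim$raw)
  endo <- sim$panel$gene[sim$panel$probe_class == "endogenous"]
  expect_setequal(norm$expr$gene, endo)
  expect_false(any(grepl("^HK_|^POS_|^NEG_", norm$expr$gene)))
})

test_that("scale factors are geometric-mean anchored and permutation-equivariant", {
  sim <- default_sim(seed = 16, n_samples = 10)
  norm <- normalize_counts(sim$raw, background_subtract = TRUE)
  expect_equal(exp(mean(log(norm$factors$housekeeping_scale))), 1, tolerance = 1e-12)
  expect_equal(exp(mean(log(norm$factors$positive_scale))), 1, tolerance = 1e-12)

  perm <- sample(seq_len(10))
  counts_p <- sim$raw
  ids <- names(sim$raw$counts)[-1]
  counts_p$counts <- sim$raw$counts[c(1, 1 + perm)]
  counts_p$controls <- sim$raw$controls[c(1, 2, 2 + perm)]
  counts_p$lane_attributes <- sim$raw$lane_attributes[perm, ]
  norm_p <- normalize_counts(counts_p, background_subtract = TRUE)
  expect_equal(norm_p$expr[c("gene", ids)], norm$expr[c("gene", ids)])
})

test_that("zero housekeeping signal names the offending sample", {
  sim <- default_sim(seed = 17, n_samples = 4)
  counts <- sim$raw
  s2 <- names(counts$counts)[3]
  counts$counts[[s2]][grepl("^HK_", counts$counts$gene)] <- 0
  expect_error(normalize_counts(counts, positive_control = FALSE), s2)
})

test_that("background subtraction floors at zero and FFPE mode lowers values", {
  sim <- default_sim(seed = 18, n_samples = 6)
  on_ <- normalize_counts(sim$raw, background_subtract = TRUE)
  off <- normalize_counts(sim$raw, background_subtract = FALSE)
  expect_true(all(as.matrix(on_$normalized_counts[-1]) >= 0))
  expect_true(all(on_$factors$background > 0))
  expect_true(all(off$factors$background == 0))
})
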