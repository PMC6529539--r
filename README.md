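# nanocrc

Molecular subtyping of colorectal cancer (CRC) on the NanoString nCounter
platform. The package implements the full computational stack behind a
reduced-gene-panel, nearest-centroid CRC assay:

- **RCC ingestion and QC** — parse nCounter lane files, check imaging,
  binding density, positive-control linearity and background.
- **Normalization** — positive-control scaling, negative-control background
  subtraction, housekeeping-gene scaling (all geometric-mean anchored),
  `log2(x + 1)`.
- **idSample-style deconvolution** — per-sample subtype weights by
  linear-kernel ν-support-vector regression against reference centroids;
  samples whose largest normalized weight strictly exceeds 70% are taken as
  single-subtype.
- **intPredict-style panel reduction** — Monte-Carlo cross-validation (50
  stratified random splits) over three gene-selection methods (prediction
  strength, PAM shrunken centroids, between/within sum-of-squares ratio)
  crossed with four classifiers (random forest, DLDA, linear and radial
  SVM); the panel size with the lowest pooled median misclassification error
  rate wins, and reduced-panel centroids are derived by PAM methodology.
- **CRCA classification** — Pearson correlation of gene-wise median-centred
  profiles against centroids of the five CRCA subtypes (goblet-like,
  enterocyte, stem-like, inflammatory, TA); a sample is *undetermined* when
  its best correlation r ≤ 0.15 or its top-two margin r₁ − r₂ ≤ 0.06.
- **Concordance statistics** — agreement percentage excluding undetermined
  calls, Fisher's exact test on the cross-tabulation, per-subtype
  equality-of-proportions tests, subtype distributions.
- **Synthetic data** — a generator with planted truth (centroid-structured
  mixtures, lane factors, control probes, RCC files) so the whole pipeline
  is testable without instrument data.

## The core statistics

Subtype weights for sample *y* against centroid matrix *C* (genes ×
subtypes, both z-scored over the shared genes) come from ν-SVR: negative
fitted weights are set to zero and the rest normalized to proportions
`p_k = max(w_k, 0) / Σ_j max(w_j, 0)`.

The misclassification error rate over *k* held-out samples is
`MCR = (1/k) Σ e_i`, with `e_i` the 0/1 error indicator; each candidate
panel size is summarized by the median MCR over all selection × prediction
draws with a bootstrap 95% interval on the median.

Classification assigns `argmax_k cor(x, C[, k])` subject to the
undetermined rules above (both thresholds inclusive).

## Worked example

```r
library(nanocrc)

cfg   <- simulation_config(n_samples = 24, noise_sd = 0.25, seed = 7)
sim   <- simulate_counts(cfg)
files <- write_rcc_files(sim, "lanes/")        # one RCC file per lane

counts <- assemble_counts(files, sim$panel)
norm   <- normalize_counts(counts)
norm
#> <nano_norm> 50 endogenous genes x 24 samples (log2)
#> housekeeping scale range: 0.9894 - 1.01

calls <- classify_subtypes(norm$expr, sim$centroids)
glance(calls)
#> # A tibble: 1 x 4
#>       n n_classifiable n_undetermined percent_classifiable
#> 1    24             24              0                  100

subtype_distribution(calls)
#> # A tibble: 5 x 3
#>   subtype          n percent
#> 1 goblet-like      5    20.8
#> 2 enterocyte       7    29.2
#> 3 stem-like        6    25
#> 4 inflammatory     3    12.5
#> 5 TA               3    12.5

glance(estimate_weights(norm$expr, sim$centroids))
#> # A tibble: 1 x 4
#>   n_samples n_selected purity_threshold mean_rmse
#> 1        24         18              0.7     0.324

truth <- tibble::tibble(sample_id = sim$truth$sample_id,
                        assigned  = sim$truth$subtype)
concordance(calls, truth)
#> <concordance_result> 100.0% (24/24 classifiable), Fisher p = 5.05e-14 (exact)
```

The housekeeping scale range near 1 shows the positive-control step already
absorbed the planted lane factors; 18/24 samples pass the strict >70%
single-subtype rule (the cohort was simulated with 80% pure samples); and
every planted label is recovered, which is the expected behaviour at this
noise level.

A command-line wrapper over the same functions is installed as
`exec/nanocrc` with subcommands `simulate`, `qc`, `normalize`, `idsample`,
`select-genes`, `classify` and `compare` (`nanocrc <cmd> --help`).

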