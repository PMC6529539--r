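---
title: "Methods: nCounter CRC subtyping with nanocrc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nCounter CRC subtyping with nanocrc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocrc)
```

# Overview

`nanocrc` implements a digital gene-expression subtyping pipeline for
colorectal cancer on the NanoString nCounter platform: lane-level QC and
normalization of raw probe counts, support-vector-regression estimation of
per-sample subtype mixture weights, Monte-Carlo cross-validated reduction of
a candidate gene panel, derivation of reduced-panel centroids, and a
nearest-centroid classifier over the five CRCA subtypes (goblet-like,
enterocyte, stem-like, inflammatory, TA) with explicit "undetermined"
rules. This vignette records the models, the tunable parameters and their
defaults, and the design decisions taken where the procedure was genuinely
open.

# Normalization model

Raw counts for probe $g$ in lane $i$ are modelled as
$x_{gi} = f_i \cdot 2^{\mu_{gi}}$, where $f_i$ is a multiplicative
lane-level technical factor (hybridization efficiency, imaging) and
$\mu_{gi}$ the underlying log2 abundance. The pipeline removes $f_i$ in two
stages, then stabilizes with a log transform:

1. **Positive-control scaling** (optional, default on): lane factor
   estimate = geometric mean of the six synthetic positive probes, which
   follow a 4-fold concentration ladder (128 down to 0.125 fM).
2. **Background subtraction** (optional, default off): per lane,
   mean + 2 SD of the negative-control probes, floored at zero. Off by
   default because fresh-frozen material has negligible background; enable
   for FFPE, where degradation inflates it.
3. **Housekeeping scaling** (always on): geometric mean of the
   housekeeping probes, the step that removes residual content-independent
   lane effects.
4. $\log_2(x + 1)$; the pseudocount of 1 keeps post-background zeros
   finite.

Both scale-factor vectors are **geometric-mean anchored** — they multiply
to one across the cohort — rather than referenced to a designated lane, so
results do not depend on lane order or on which sample arrived first.
Re-estimating factors on already-normalized counts returns factors of 1 (to
1e-9; this idempotence is tested). Lane-level QC flags use
platform-conventional thresholds, all configurable via `qc_thresholds()`:
fields-of-view fraction ≥ 0.75, binding density in [0.1, 2.25] spots/µm²,
positive-control log-log linearity R² ≥ 0.95, and a low-signal flag when
the median endogenous count falls below background. These thresholds and
the background rule are reconstructions of common nCounter practice, and
are documented as such.

# Subtype mixture weights (SVR deconvolution)

A bulk tumour profile is treated as an approximate linear mixture of
subtype reference profiles. For each sample, the expression vector over the
centroid genes is regressed on the centroid matrix columns with
linear-kernel ν-SVR, following the CIBERSORT convention: the sample vector
and each centroid column are z-scored across the shared genes, the fit is
run over ν ∈ {0.25, 0.5, 0.75}, and the fit with the lowest RMSE between
fitted and observed values is kept. Negative weights denote subtypes absent
from the sample: they are zeroed, and the surviving weights renormalized to
proportions. A sample *represents a single subtype* when its maximum
proportion strictly exceeds 0.70 — the boundary value 0.70 itself does not
pass.

Two numerical details:

- **No-signal sentinel.** When the best fit explains less than
  `min_explained = 0.05` of the standardized sample variance (or every raw
  weight is non-positive), the sample is given the all-zero proportion
  sentinel. This mirrors the exact non-negative-least-squares solution on a
  profile orthogonal to the centroid space, which is identically zero,
  whereas the ε-insensitive SVR loss leaves tiny spurious coefficients
  (|w| ≲ 0.1 on the standardized scale) on such profiles. The tests verify
  both routes against a `pracma::lsqnonneg` oracle.
- **Ties** at the maximum proportion resolve to the subtype earliest in
  canonical order (`crca_subtypes()`), with a warning, for determinism.

Standardization makes the proportions invariant to positive rescaling of
the sample vector. Gene coverage is the intersection of sample and centroid
genes, with a minimum of 10 shared genes (configurable) — the panel is
fixed in practice, so missing genes signal a panel mismatch rather than
ordinary missingness.

# Panel reduction by Monte-Carlo cross-validation

Candidate panels are evaluated by repeated stratified random splitting
(default 50 repeats, 2/3 training / 1/3 test per class — the conventional
split at cohort sizes around two hundred). In each split, each selection
method ranks genes **on the training partition only**:

- **BW** — between/within group sum-of-squares ratio
  $\sum_k n_k(\bar x_k - \bar x)^2 / \sum_k\sum_{i \in k}(x_i - \bar x_k)^2$,
  with 0/0 defined as 0 and positive/0 as $+\infty$.
- **PAM** — shrunken-centroid statistic
  $d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k(s_i + s_0))$,
  $m_k = \sqrt{1/n_k - 1/n}$, $s_0$ = median pooled SD; genes ranked by
  $\max_k |d_{ik}|$.
- **PS** — prediction strength, reconstructed as a one-vs-rest
  signal-to-noise score $\max_k |\bar x_k - \bar x_{\text{rest}}| /
  (s_k + s_{\text{rest}})$. The original criterion is cited in the
  literature without a closed form; this reconstruction is flagged as the
  package's own.

Each classifier is then trained on the training partition over the selected
genes and scored on the held-out samples by the misclassification error
rate $\mathrm{MCR} = \frac1k \sum_i e_i$. Classifiers: random forest (500
trees, $\sqrt p$ features per split), DLDA (implemented from its closed
form — class means, pooled per-gene variances, diagonal Gaussian
discriminant with training priors; variances floored at 1e-12), and linear
and radial SVM (C = 1, radial γ = 1/p). These hyperparameters are
conventional defaults and are configurable.

Per panel size, the MCR draws from **all** selection × prediction
combinations are pooled; the size with the lowest pooled median wins, ties
resolving to the smaller panel. The 95% interval on the median is a
percentile bootstrap with 2000 resamples — a minimal reconstruction of a
credible interval on the median, labelled as such. Splits and classifier
randomness all derive from the single pipeline seed, and identical seeds
give bitwise-identical draws. A canary test verifies no information
leakage: a gene that separates classes only on the held-out partition does
not lower the error.

Reduced-panel centroids are derived by the PAM construction
$\bar x_i + m_k (s_i + s_0)\, \mathrm{sign}(d_{ik}) (|d_{ik}| - \Delta)_+$
with shrinkage $\Delta = 0$ by default (i.e. class means on the input
scale), since whether the published centroids used nonzero shrinkage is not
recoverable; $\Delta$ is a parameter.

# Nearest-centroid classification

Profiles are gene-wise median-centred across the classification batch, and
each sample is Pearson-correlated with every centroid column over the
shared genes (at least 30 by default). The best-correlated subtype is
assigned unless the sample is *undetermined*:

- $r_1 \le 0.15$ — too far from every centroid (`low_correlation`);
- $r_1 - r_2 \le 0.06$ — ambiguous between the top two (`low_margin`).

Both comparisons are inclusive, so a profile exactly on a threshold is
undetermined; numerical argmax ties fall under the margin rule without any
explicit tie-breaking. Median centring is a cohort operation: a single
sample centres to all zeros and is unclassifiable, so batches of fewer than
5 samples require a frozen `reference_medians` table (true single-sample
mode). Centring is per batch/platform; correlations are invariant to
per-sample affine transforms applied after centring, which the tests
assert, along with exact agreement (to 1e-12) with a brute-force
implementation of the Pearson formula.

# Concordance machinery

Agreement between two call sets is computed over the samples classifiable
in **both** sets (pairwise-complete; the natural reading when the two
classifiers disagree about which samples are undetermined), as
$100 \cdot n_{\text{agree}} / n_{\text{classifiable}}$, with Fisher's exact
test on the cross-tabulation — exact up to a classifiable total of 200,
seeded Monte-Carlo (10^5 draws) beyond, with the method recorded in the
result. Per-subtype distribution shifts across classifiers use the
chi-squared equality-of-proportions test (`stats::prop.test`; Yates
correction in the two-classifier case), as "proportion test" is not
otherwise pinned down.

# The synthetic-data generator

`simulation_config()` defines the simulated study conditions; its defaults
are fixed once and are not tuned against test outcomes:

- five equiprobable subtypes; 8 marker genes per subtype at +2 log2 over a
  baseline of 8; 10 uninformative genes; block-structured centroids whose
  columns correlate below 0.3;
- 80% pure samples, the rest two-way mixtures with mixing fraction 0.7 —
  mixed-subtype tumours are a documented feature of CRC cohorts;
- gene-level Gaussian noise of 0.25 log2 units (roughly an eighth of the
  marker effect, a realistic bulk-profiling noise floor);
- lane factors log-uniform in [0.5, 2];
- 10 housekeeping probes at log2 abundance 10, constant in log-mean —
  stable reference genes by construction — carrying only the lane factor
  and count rounding;
- the standard 4-fold positive-control ladder (top rung 8192 counts at
  lane factor 1, so the lowest rung still counts in the single digits) and
  Poisson(2) negative controls;
- counts are rounded lognormal by default (the planted-truth algebra stays
  exact); a negative-binomial option (`count_model = "nb"`) adds
  overdispersion when count-distribution realism matters.

What the generator does **not** emulate: probe-specific affinities,
FFPE-specific degradation beyond an elevated `noise_sd`, cross-hybridization,
or cohort composition effects. Passing recovery tests on this generator
therefore demonstrates correctness of the algorithms under their own data
model, not clinical performance on tissue.

# Problem sizes in the checks

The automated checks run at desk scale, chosen to make the properties
sharp while staying light: 1000 random 38-gene profiles for the
classifier-versus-oracle comparison, 200 two-way mixtures for weight
recovery (MAE ≤ 0.05 at noise 0.1), 24 lanes for lane-factor recovery
(within 2%), cohorts of 60–100 samples and 50 Monte-Carlo repeats for the
panel-reduction checks (median MCR 0 on separable data; 0.8 ± 0.05 on
label-permuted data with five balanced classes at n = 500), and full
enumeration of every 2×2 contingency table with n ≤ 12 (plus sampled 3×3
tables) for the Fisher test.

# Known limitations

- The published reduced gene panel itself cannot be reproduced without the
  original training cohorts; the package reproduces the *procedure* and
  verifies it on planted-truth data.
- QC thresholds and the background rule are reconstructions of platform
  convention, not the assay's exact laboratory protocol.
- The PS gene score is a reconstruction (see above).
- Classification depends on the co-normalized batch through median
  centring; single-sample use requires a frozen reference-median table and
  inherits its cohort's composition.
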