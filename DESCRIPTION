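Package: nanocrc
Title: NanoString nCounter Subtyping Toolkit for Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for gene-expression subtyping of colorectal
    cancer on the NanoString nCounter platform. Parses RCC lane files, performs
    control-probe quality control and housekeeping-based normalization, estimates
    per-sample subtype mixture weights by support vector regression against
    reference centroids, reduces candidate gene panels by Monte-Carlo
    cross-validated misclassification error, derives shrunken-centroid reference
    profiles, assigns samples to the five CRCA subtypes by nearest-centroid
    Pearson correlation with explicit undetermined rules, and quantifies
    concordance between classifiers. A synthetic-data generator with planted
    ground truth makes the whole pipeline testable without platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
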