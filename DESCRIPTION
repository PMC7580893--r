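Package: nuctrackr
Title: Semi-Automated 3D Nucleus Tracking in Time-Lapse Fluorescence Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracking-by-detection of fluorescently labelled cell nuclei in 3D
    time-lapse movies of organoids and other dense epithelial tissues. Nucleus
    centers are detected with a small 3D heatmap-regression network whose
    convolutions receive absolute-coordinate channels, refined by 3D Gaussian
    mixture fits that also yield a nucleus volume proxy, and linked across time
    with a globally optimal division-aware min-cost formulation. A rule-based
    error checker flags improbable events for manual curation, a matching-based
    evaluator computes detection and link precision/recall at a 5 micrometer
    threshold, and a synthetic movie generator with known ground truth makes
    every stage testable without real data. Tracking data round-trips through a
    JSON schema and the Cell Tracking Challenge layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: python3 with scipy (>= 1.9) on PATH, used for the exact
    integer-programming backend of the link solver.
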