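Package: pxsal
Title: Point-Supervised Multiscale Saliency Detection for Pelvic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised detection of trauma-related findings on pelvic
    radiographs from point annotations. Converts annotation points into
    multi-resolution disk supervision masks, trains a feature-pyramid saliency
    network with a pixel-wise multiscale binary cross-entropy loss under
    fivefold cross-validation, performs bagged test-time-augmentation ensemble
    inference producing an image-level probability and a fused localization
    map, and provides the accompanying statistical battery: ROC/PR areas with
    bootstrap confidence intervals, Youden-J operating points, confusion
    metrics, per-category breakdowns, McNemar paired comparisons, and a
    three-class reader-study harness. Includes a synthetic pelvis-phantom
    generator with insertable lesions so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
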