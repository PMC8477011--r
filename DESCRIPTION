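Package: mkfusion
Title: Multiple Kernel Learning for Multimodal Neuroimaging Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-level fusion of tabulated neuroimaging-derived features for
    case/control classification. Provides a synthetic multimodal cohort
    generator, empirical-Bayes location-scale batch harmonization with a
    fit/apply split, all-relevant feature selection with shadow features and a
    cross-run binomial selection-stability test, per-modality Gram-matrix
    construction (linear and RBF kernels) with convex combination over a weight
    simplex, an SMO solver for the multiple-kernel SVM dual with Platt
    probability calibration, and a repeated nested cross-validation harness
    with unimodal, early-fusion and multi-kernel baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    sva,
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
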