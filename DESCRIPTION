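Package: plantarqc
Title: Quality Control for Plantar Pressure Maps via Normative Statistical
    Mapping and an Explainable Convolutional Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting technical outliers (acquisition errors,
    double-foot captures, inverted orientation, swapped laterality labels)
    in standardized 64x64 plantar pressure maps.  Implements two
    complementary detectors: a non-parametric normative statistical map
    with cluster-based permutation control of the family-wise error rate,
    operating on affinely registered maps, and a five-class convolutional
    neural network with a laterality embedding, explained through
    Shapley-additive per-pixel attributions.  Includes a synthetic
    plantar-pressure generator with the four canonical outlier
    transformations, a nested grouped stratified cross-validation harness
    with MCC/F1 reporting, and analysis utilities for semantic-differential
    expert surveys (paired signed-rank tests, bootstrap confidence
    intervals, post-hoc power).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
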