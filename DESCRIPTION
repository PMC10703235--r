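Package: hclocal
Title: Hierarchical Cluster-Based Local Regression for Spectral and
    Simulated Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical cluster-based (HC) regression: a global partial
    least squares regression (PLSR) model is fitted by NIPALS, its X-scores
    are clustered by fuzzy c-means (alternatively hierarchical agglomerative
    or spectral clustering), one local regressor (PLSR, support vector
    regression, a small 1D convolutional network or a two-layer recurrent
    network) is calibrated per cluster, and new samples are routed to a
    cluster by a classifier (FCM membership, LDA, QDA or naive Bayes) and
    predicted by the closest local model.  Includes per-cluster feature
    importance (PLS loadings, VarGrad input-gradient variance, permutation
    importance), an FT-IR style preprocessing chain (replicate averaging,
    Savitzky-Golay derivatives, extended multiplicative signal correction,
    region cropping, centring/scaling), and generators for a three-cluster
    Friedman-function benchmark and synthetic infrared-like spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
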