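Package: pbtrans
Title: PB-Transformed Tests for Correlated and Heteroscedastic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hypothesis tests for regression-type problems with correlated
    observations and heterogeneous variance, built on the PB-transformation:
    a whitening map (B) followed by a unique orthogonal rotation (P) that
    reduce the original problem to an equivalent one-sample location test on
    independent, equal-variance values. Includes a moment-based estimator of
    the exchangeable within-block correlation with Olkin-Pratt bias
    correction, Kenward-Roger-style effective degrees of freedom, parametric
    (t) and rank-based (Wilcoxon signed rank) tests, a semiparametric data
    generator with a simulation harness (type-I error, power, ROC/AUC), and
    a vectorized runner for feature-by-feature testing of expression
    matrices with partially paired samples and sequencing-depth weights.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
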