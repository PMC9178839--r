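Package: firthgee
Title: Firth-Type Penalized and Augmented Generalized Estimating Equations
    for Clustered Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marginal logistic regression for clustered binary outcomes with
    bias-reduced, separation-robust estimation. Implements ordinary generalized
    estimating equations (GEE), penalized GEE (a Firth-type modification of the
    estimating function), and iterated and single-step augmented GEE (data
    augmentation with generalized-hat-matrix weights), together with Firth's
    logistic regression, sandwich covariance estimation with the Morel
    small-sample correction, t-based confidence intervals, a linear-programming
    separation check, and a simulation harness for clustered binary data with
    latent-threshold dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
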