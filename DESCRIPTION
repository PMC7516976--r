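Package: dpdcusum
Title: Robust Change-Point Tests for Integer-Valued Time Series via
    Density Power Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Minimum density power divergence estimation (MDPDE) for
    integer-valued GARCH-type count time series whose conditional
    distribution belongs to a one-parameter exponential family (Poisson,
    negative binomial, geometric), and robust CUSUM-type change-point
    tests built from the divergence objective. Includes the classical
    score-vector CUSUM test as a comparator, critical values of the
    supremum of a squared Brownian bridge norm, additive-outlier
    contamination generators, a Monte Carlo size/power experiment
    harness, and a return-times-of-extreme-events constructor for
    real-valued series.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
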