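Package: mqre
Title: M-Quantile Random-Effects Regression for Two-Level Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust modelling of a continuum of location parameters
    (M-quantiles, indexed by q) of the conditional distribution of a
    continuous response in two-level clustered or longitudinal data.
    Fits the M-quantile random-intercepts model by solving robust
    estimating equations: a Newton-Raphson step for the q-specific fixed
    effects and a positivity-preserving fixed-point iteration for the two
    variance components, with asymmetric Huber influence functions.
    Includes single-level M-quantile regression fitted by iterative
    weighted least squares, robust prediction of random effects through a
    Fellner-type equation, Taylor/sandwich standard errors with
    cluster-level middle matrix, and a Monte Carlo evaluation module
    covering four error-generation scenarios with relative-bias and
    relative-efficiency summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
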