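Package: multicoding
Title: Multiplicity-Adjusted Tests for Alternative Codings of a Continuous Covariate in Generalized Linear Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: When the functional form linking a continuous risk factor to an
    outcome is unknown, analysts commonly try several codings of the variable
    (dichotomizations at quantiles, multi-class categorizations, Box-Cox
    powers, fractional polynomials) and keep the one with the smallest
    p-value. This practice is a multiple-testing problem. multicoding fits
    the null generalized linear model (adjustment covariates only), computes
    Rao score tests for every candidate coding, and adjusts the minimum
    p-value by four methods: Bonferroni, the exact asymptotic maxT correction
    based on the joint multivariate-normal distribution of the score
    statistics, a permutation minP procedure, and a parametric-bootstrap minP
    procedure. It reports the best coding together with the adjusted
    p-values, and ships a synthetic-data generator for nested case-control
    style scenarios so every procedure can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
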