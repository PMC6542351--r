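Package: kpsize
Title: National Key Population Size Estimation from Incomplete Subnational Direct Estimates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the national size of hidden key populations (female sex
    workers, men who have sex with men, transgender women) when direct
    municipal size estimates are available only for a purposively selected
    subset of municipalities augmented by a smaller random sample. The
    missing-count problem is handled with inverse probability of sampling
    weights, multiple imputation pooled by Rubin's rules, and a doubly robust
    augmented IPSW estimator, all built on Poisson regression with a
    log-denominator offset. Includes restricted quadratic spline bases,
    triangulation-based interpolation of geolocated survey-cluster indicators
    onto administrative units, positivity and covariate-balance diagnostics,
    a synthetic-country generator with known ground truth, and a factorial
    simulation framework for bias, coverage, and double-robustness checks.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
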