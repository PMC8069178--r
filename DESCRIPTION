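Package: metsynflux
Title: Clamp Tracer Kinetics, CVD Risk and Metabolite Screening for Metabolic-Syndrome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for cross-sectional metabolomics studies of
    treatment-naive metabolic-syndrome men. Provides a synthetic cohort
    generator with known ground truth (clinical records, log-normal
    metabolite abundances with left-censored missingness, one-pool clamp
    tracer time courses), metabolite preprocessing (median rescaling and
    half-minimum imputation), Steele-equation flux estimation and lipolysis
    suppression from hyperinsulinemic euglycemic clamp tracer data,
    Framingham 10-year general cardiovascular risk scoring, FDR-controlled
    nonparametric metabolite screening, and a nested cross-validated
    gradient-boosted-tree classification harness with random sanity
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
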