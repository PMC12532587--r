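Package: echosens
Title: Echocardiographic Repeated-Measures Analysis with Pattern-Mixture
    Multiple-Imputation Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the longitudinal analysis of echocardiographic
    parameters in randomized trials of transthyretin amyloidosis with
    cardiomyopathy (ATTR-CM). Derives guideline echocardiographic parameters
    (Devereux left-ventricular mass, biplane Simpson volumes and ejection
    fraction, LV outflow-tract stroke volume, Doppler ratios) from raw
    measurements; fits the mixed model for repeated measures (MMRM) of change
    from baseline with an unstructured within-subject covariance by REML and
    reports least-squares mean treatment contrasts with Satterthwaite degrees
    of freedom; and implements a four-pattern pattern-mixture
    multiple-imputation sensitivity analysis (worst-decile sampling after
    death, Markov-chain Monte Carlo imputation under missing-at-random,
    retrieved-dropout regression and copy-reference imputation) pooled by
    Rubin's rules. A seeded synthetic-trial generator reproduces the data
    structure of a two-arm ATTR-CM trial with on-/off-treatment missingness
    so that every stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
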