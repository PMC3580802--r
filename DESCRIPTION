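Package: ebdose
Title: Empirical Bayes Drug Dosage Individualization with
    Random-Intercept Linear Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for individualizing drug dosages in chronic-disease
    therapeutic drug monitoring using a random-intercept linear model of
    log-transformed steady-state pharmacokinetic or pharmacodynamic
    responses.  Provides restricted maximum likelihood (REML) and maximum
    likelihood (ML) fitting of the population model, closed-form empirical
    Bayes (BLUP) prediction of patient-specific intercepts, an iterative
    Bayesian-feedback dosing algorithm with therapeutic-window Bayes-risk
    optimality, an omega-optimality framework including Monte Carlo
    computation of the minimum number of blood samples, a traditional
    proportional dose-adjustment comparator, relative-percentile effect
    sizes and dose-correction factors for covariates, a three-condition
    variance-decomposition screen for pharmacogenomic covariates, and a
    synthetic-population simulator for head-to-head comparison of dosing
    strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
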