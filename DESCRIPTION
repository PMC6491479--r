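Package: hbametab
Title: Bayesian Lognormal Regression of Circulating Metabolites on HbA1c
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ethnicity-stratified association analysis of circulating
    metabolite concentrations (NMR amino acids, ketone bodies and
    lipoprotein subclass particle concentrations) with glycated
    hemoglobin (HbA1c). Fits, per metabolite, a Bayesian lognormal
    regression with ethnicity-specific intercepts and HbA1c slopes,
    covariate adjustment (sex, age, diabetic status, BMI), and full
    Bayesian imputation of two kinds of missing data: concentrations
    below the limit of detection (imputed as parameters truncated
    between zero and the minimal observed value) and values rejected
    by quality control, plus missing covariates with exponential
    hyperpriors on ethnicity-specific imputation means and standard
    deviations. Inference is by Hamiltonian Monte Carlo with posterior
    means and equal-tailed 95 percent credible intervals, split R-hat
    and effective-sample-size diagnostics. Includes a synthetic
    three-group cohort generator with exported ground truth for
    parameter-recovery and interval-coverage validation, and reporting
    of per-subgroup coefficient tables and baseline-characteristics
    summaries.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
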