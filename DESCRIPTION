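Package: mederrisk
Title: Medication Error Risk Prediction and Triage Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and internal validation of a fractional-polynomial
    logistic model predicting clinically significant in-hospital medication
    errors, together with tools to evaluate its clinical impact. Includes a
    seeded synthetic-cohort generator emulating an adult inpatient population,
    NCC MERP based severity grading of medication-error records, univariate
    and association-rule predictor screening over ATC drug-class indicators,
    multivariable fractional-polynomial logistic regression with permissive
    backward elimination, Harrell-style bootstrap optimism correction with
    uniform shrinkage, a frozen published-coefficient risk scorer, and a
    simulated randomized-controlled-trial engine comparing model-based patient
    triage against single-criterion (age, drug-count) selection across
    pharmacist coverage scenarios, reporting interception rates and numbers
    needed to treat.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
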