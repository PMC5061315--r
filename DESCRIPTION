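Package: cvrecal
Title: Recalibration and Validation of 10-Year Cardiovascular Risk Equations
Version: 0.1.0
Authors@R:
    person("cvrecal", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Implements the ACC/AHA Pooled Cohort Equations for 10-year
    atherosclerotic cardiovascular disease (ASCVD) risk and the ESC SCORE
    for 10-year cardiovascular mortality, together with
    calibration-in-the-large recalibration (an intercept-level log-odds
    correction), a full calibration and discrimination evaluation toolkit
    (observed event frequency, incidence rates, overestimation, decile
    calibration tables, Harrell's C for censored data, ROC export),
    k-fold cross-validation, a synthetic-cohort generator emulating
    population-based German cohort baseline structure, and a config-driven
    command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
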