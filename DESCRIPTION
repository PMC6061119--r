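Package: demrisk
Title: External Validation of Dementia Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Head-to-head external validation of published dementia risk
    prediction models (CAIDE, BDSI, ANU-ADRI and the Dementia Risk Score) in
    elderly community-dwelling cohorts. Implements the four point-based and
    regression-based scoring systems exactly as published, together with the
    survival machinery needed to validate them: Harrell's concordance
    statistic for censored data with bootstrap confidence intervals, horizon
    truncation, calibration intercept/slope with decile plots, intercept and
    baseline-survival recalibration, chained-equations multiple imputation
    with Rubin's rules, and a seedable synthetic two-wave cohort generator
    with Gompertz dementia and mortality hazards so the whole pipeline can be
    exercised without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
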