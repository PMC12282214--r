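Package: deskbreaks
Title: Workplace Active-Break Intervention Analysis with Overlap-Weighted
    Propensity Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for quasi-experimental workplace
    sitting-reduction studies: processes epoch-level accelerometer data into
    occupational sedentary-behavior and physical-activity metrics (MET
    cut-point classification, non-wear detection, bout detection,
    standardization to an 8-hour workday), scores mental-health and job
    performance questionnaires (K6, work engagement, absolute presenteeism),
    performs multiple imputation by chained equations with predictive mean
    matching, and estimates the average treatment effect in the overlap
    population (ATO) via propensity-score overlap weighting with an
    M-estimation sandwich variance and Rubin's-rule pooling. Includes a
    calibrated synthetic two-arm cohort generator so the whole pipeline is
    testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
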