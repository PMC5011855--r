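Package: mcidpr
Title: Minimal Clinically Important Differences for COPD Health-Status
    Instruments in Pulmonary Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the minimal clinically important difference (MCID) of
    the CCQ, CAT and SGRQ health-status questionnaires from pre/post
    pulmonary-rehabilitation cohorts. Implements three anchor-based methods
    (patient-referencing on a global rating of change, criterion-referencing
    on exacerbation during rehabilitation, questionnaire-referencing with
    regression, achiever/failure group means and ROC cut-point selection,
    including iterative anchor revision), three distribution-based estimators
    (SEM, 1.96 SEM, half the change-score standard deviation), pooled
    combiners for total and domain scores, and a calibrated synthetic cohort
    generator so the full pipeline runs without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
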