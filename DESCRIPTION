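Package: htindex
Title: Hypertensive Index Scoring and Outcome Analysis for Hypertension
    Intervention Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Hypertensive Index (HTi), a composite score of
    excess systolic blood pressure and antihypertensive medication load,
    together with comparator scores, a four-group treatment-response
    classification for paired baseline/discharge cohorts, rank-based ROC
    comparison of candidate improvement scores, seeded synthetic cohort
    generation from published group-level moments, cohort CSV input and
    output with validation, and summary-table reporting with a
    normality-gated test-selection policy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
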