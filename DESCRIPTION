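Package: watbarthel
Title: Predicting the Barthel Index from Wearable Activity Tracker Step Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the Barthel Index (BI), a 0-100 score of
    independence in activities of daily living, from step-count streams
    recorded by consumer wrist-worn activity trackers. The package turns raw
    per-minute step and heart-rate samples into mean 24-hour activity
    profiles, reduces each profile to segment-maximum mobility features plus
    walking-aid indicators, fits an interpretable variance-reduction
    regression tree with cross-validated hyperparameters, converts predicted
    BI values to dependence classes (total / severe / moderate-or-mild), and
    scores both the regression and the derived classification. A synthetic
    actigraphy generator produces cohorts with circadian activity bursts
    anchored to meal times, walking-aid-dependent step undercounting,
    heart-rate-linked missingness, and early dropout, so the whole pipeline
    can be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rpart,
    ggplot2
Config/testthat/edition: 3
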