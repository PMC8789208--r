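Package: murtree
Title: Regression-Tree Prediction of Medical Usage Rates at Mass Gatherings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop and validate prediction models for onsite medical
    usage at mass-gathering events. Builds event-level patient presentation
    rates (PPR) and transfer-to-hospital rates (TTHR) per 10,000 attendees from
    patient-encounter registries, fits recursive-partitioning regression trees
    over categorical event predictors with 10-fold cross-validated
    hyperparameter selection, surrogate splits and variable importance, applies
    a proportional linear temperature adjustment for outdoor summer events,
    cascades the fitted PPR tree into a TTHR model, and evaluates calibration
    (squared correlation with confidence intervals, 25 percent deviation bands)
    on development, temporal and external datasets. Includes a synthetic
    registry generator with known ground truth for end-to-end testing and
    parameter-recovery studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
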