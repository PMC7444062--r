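Package: apatools
Title: Scoring and Validation Toolkit for the Activity Preference Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Activity Preference Assessment (APA), a computerized
    forced-choice task that quantifies children's implicit preference for
    sedentary relative to physical leisure activities. Generates the blocked,
    counterbalanced trial schedule over the 16-activity catalog; computes the
    reaction-time-weighted implicit bias score and explicit liking/wanting
    summaries; implements the study measurement rules used for validation
    (Evenson accelerometer cut-points and wear-validity checks, free-play
    observation scoring, VO2peak attainment criteria, body-composition indices,
    weight-status classes, and Likert questionnaire scoring); provides the
    validation statistics layer (Pearson and partial correlations, two-way
    mixed absolute-agreement ICC, independent t-tests); and ships synthetic
    respondent and cohort simulators so every stage is testable without
    participant data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
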