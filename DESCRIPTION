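Package: tdcontrol
Title: Treatment Duration Control: Relative-Change Outcome Monitoring for
    Trials with Variable Treatment Duration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Treatment Duration Control (TDC) index, a
    relative-change outcome measure for routine outcome monitoring and
    randomized controlled trials in which treatment duration is patient- and
    therapy-specific. Provides the Contrast transform of score ratios and its
    factor conversions, adaptive selection of basic and added reference items
    under smallest-detectable-difference thresholds, the visit-by-visit
    decision engine with responsiveness and success cut-offs and the
    anamnestic discrepancy rule, calibration of cut-offs from a
    maximal-severity score profile against an upper limit of functional
    status (including weighted-percentile estimation of that limit), and a
    synthetic-cohort simulator with regression-to-the-mean diagnostics for
    validating the whole procedure.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
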