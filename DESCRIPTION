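Package: glucirc
Title: 24-Hour Variation in Blood Glucose During Continuous Enteral
    Nutrition in the ICU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the 24-hour pattern in blood glucose of
    intensive-care patients receiving continuous enteral nutrition from
    timestamped electronic-health-record event tables. Implements cohort
    selection and measurement-level cleaning (sample-type validity limits,
    timestamp resolution, simultaneous-measurement deduplication),
    pharmacokinetically corrected exposure-window matching of nutrition,
    insulin, dextrose and glucocorticoid administrations to each glucose
    measurement, a nested random-intercept linear mixed-effects model
    sequence with likelihood-ratio comparisons and hourly estimated-marginal-
    means profiles, a gradient-boosted-tree cross-check with per-feature
    attribution values, subgroup profiling, and a synthetic EHR cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    emmeans,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
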