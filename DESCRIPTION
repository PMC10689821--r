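Package: thyrowatch
Title: Predicting Thyrotoxicosis from Sleep Heart-Rate Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end system for predicting thyrotoxicosis (elevated
    free thyroxine) from wearable-derived sleep heart-rate data. Joins
    thyroid function tests to the sleep heart-rate window preceding each
    blood draw, builds paired-change features between a referred test and
    a target date (distribution moments, Jensen-Shannon divergence, and a
    derived mean-change/TSH quotient), augments training data by linear
    interpolation of adjacent tests, trains a quantile-transformed
    gradient-boosted tree classifier, and evaluates it with a modified
    leave-one-out cross-validation that excludes every case touching the
    held-out target pair. Includes a synthetic cohort generator emulating
    treated thyroid-dysfunction patients so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
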