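Package: hbpcount
Title: Count-Based Decision Rules for Home Blood Pressure Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for judging whether home blood pressure (HBP) achieves the
    135/85 mmHg target from counts of high readings rather than from the mean.
    Implements the high-BP count and count-to-total (C/T) ratio statistics and
    the half-of-K decision rule; a factorial simulation study of their
    diagnostic accuracy (ROC curves, C-statistics with DeLong and bootstrap
    confidence intervals, Youden-index thresholds); bootstrap and linear
    mixed-model comparison of performance across series lengths and reading
    variability; linear and logit calibration models that estimate mean blood
    pressure from count statistics with t-based 95% prediction intervals and
    rule-in/rule-out thresholds; and a validation pipeline for real home
    blood pressure monitoring records (reading, exclusions, stratified
    evaluation), together with a synthetic-cohort generator emulating the
    hierarchical structure of such data.
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
    lme4,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
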