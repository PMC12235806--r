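Package: pmprecision
Title: Sample Size for Precise and Stable Individual Risk Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans the sample size needed to develop or update a binary-outcome
    clinical risk prediction model so that individual-level risk estimates are
    precise and classification is stable. Decomposes the variance of logistic
    regression estimates into the sample size and Fisher's unit information
    matrix computed over an assumed case-mix, and from an assumed 'core model'
    anticipates 95% uncertainty intervals, misclassification probabilities at
    clinical risk thresholds, and mean absolute prediction error for any
    candidate sample size; inverts the relationship to find the sample size
    achieving target interval widths; and computes the established
    population-level minimum sample size criteria for comparison. Includes a
    declarative generator for synthetic cohorts from categorical cell tables
    and correlated continuous summaries, calibration of a core model to a
    target prevalence and C-statistic, subgroup (fairness) summaries, and
    prediction- and classification-instability plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    readr
Config/testthat/edition: 3
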