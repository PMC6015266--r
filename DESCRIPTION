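Package: wearstress
Title: Multimodal Wearable and Mobile Phone Features for Stress and Mental Health Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and evaluation pipeline for month-long ambulatory
    studies of perceived stress and mental health in which participants wear a
    wrist sensor (skin conductance, skin temperature, acceleration) and carry a
    phone that logs calls, SMS, screen events and location. Implements FIR
    low-pass filtering and slope-threshold detection of skin conductance
    responses, 30-second epoch features over clinically motivated time windows,
    the Sleep Regularity Index, phone-usage and Gaussian-mixture mobility
    features, Perceived Stress Scale and SF-12 Mental Component Summary group
    construction with class balancing, and nested leave-one-cohort-out
    classification with a t-test prefilter, sequential forward feature selection
    and SVM/LASSO models, reported with adjusted-Wald confidence intervals.
    Ships a synthetic cohort generator with a latent stress trait so the whole
    pipeline is testable without access to any real cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    signal,
    e1071,
    glmnet,
    mclust,
    yaml,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
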