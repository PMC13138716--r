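Package: steptraj
Title: Latent Class Trajectory Analysis of Daily Step Counts and Weight Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Classifies roughly one year of daily step-count records into
    latent trajectory classes and relates the trajectories to a binary
    weight-loss outcome. Provides preprocessing of raw device records
    (device deduplication, range filtering, weekly averaging, cohort
    eligibility), maximum-likelihood estimation of a latent class mixed
    model with class-specific quadratic mean curves and a shared random
    intercept (EM with a damped-Newton polish), a three-condition rule for
    choosing the number of classes, archetype labeling of fitted
    trajectories (UP, DOWN, UP/DOWN, FLAT), logistic regression of 3
    percent weight loss on trajectory class with Wald inference, and a
    synthetic cohort generator with known ground truth for testing every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
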