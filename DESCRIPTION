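Package: noveltybandit
Title: Novelty-Seeking Bandit Task Simulation, Reinforcement-Learning
    Model Fitting, and Clinical Moderation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a three-armed bandit task in which stimuli are
    periodically replaced by novel alternatives, fits a delta-rule
    reinforcement-learning model (learning rate and softmax inverse
    temperature) to choice data by maximum likelihood, estimates
    novelty propensity from lag-2 novel choices, builds reward
    prediction error modulated fMRI design matrices with motion
    censoring and percent-signal-change scaling, and provides the
    clinical statistics used in adolescent substance-use research:
    Rankit transformation, partial correlation, Steiger's z, variance
    inflation factors, mixed-design ANCOVA on region-of-interest
    coefficients, and moderation analysis with Johnson-Neyman regions
    of significance. Includes a synthetic-cohort generator with
    planted effects for end-to-end power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
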