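Package: betalearn
Title: Sensorimotor Beta Oscillations and Motor Skill Learning Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between sensorimotor-cortex
    beta oscillations (15-30 Hz) and motor skill learning. Provides a
    synthetic-cohort generator (continuous tracking-task learning curves and
    event-related oscillatory EEG with configurable movement-related beta
    desynchronization and post-movement beta rebound), behavioural scoring by
    block root-mean-square error with regression-corrected session endpoints,
    a Morlet wavelet time-frequency pipeline with baseline percent-change
    rescaling and electrode-pool beta measures, and group-level inference:
    mixed-design ANOVA with partial eta squared, Bonferroni post hocs, and
    stepwise regression with leave-one-out cross-validation and permutation
    significance for predicting future motor performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    signal,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    readr
Config/testthat/edition: 3
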