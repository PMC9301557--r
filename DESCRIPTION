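Package: lungscreen
Title: Cost-Effectiveness Modelling of Low-Dose CT Lung Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov state-transition cost-effectiveness model of low-dose
    computed tomography (LDCT) lung cancer screening in heavy smokers,
    following a closed cohort through annual cycles of disease onset, stage
    progression, screen-based and symptomatic detection, and death. Provides
    a validated, config-driven parameter set (age-banded incidence and
    mortality, smoking prevalence, test accuracy, stage transition
    probabilities, utilities and costs), derivation of heavy-smoker incidence
    from population rates, a deterministic cohort engine with discounted cost
    and QALY accrual, a screening-strategy grid (one-time and annual
    screening at start ages 50-74 versus no screening) with incremental
    cost-effectiveness ratios and threshold classification, one-way
    (tornado) and probabilistic (beta/gamma) sensitivity analyses, and a
    synthetic-data module emulating a screening registry and stage-labelled
    treatment-cost claims together with an independent individual-level
    microsimulation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
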