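Package: castsim
Title: Simulation and Analysis of an Effort-Based Choose-and-Solve Task
Version: 0.1.0
Authors@R: person("CAST", "Maintainers", email = "castsim@example.org",
    role = c("aut", "cre"))
Description: Simulates the choose-and-solve task (CAST), an effort-based
    decision-making paradigm in which participants repeatedly choose between
    an easy low-reward and a hard high-reward problem and then solve the
    chosen problem under time pressure, with hard-problem difficulty governed
    by a 2-up-1-down adaptive staircase. Provides synthetic problem banks,
    generative agent models with anxiety-modulated effort costs, cohort
    synthesis with correlated trait scores, session simulation for the three
    study designs, scoring of hard-choice probability (HCP) and average
    difficulty level (ADL) with exclusion rules, and a statistical layer
    (Fisher-z correlation inference, power arithmetic, domain-by-anxiety
    interaction regression, binomial regression, test-retest reliability)
    for parameter-recovery experiments on fully synthetic cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
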