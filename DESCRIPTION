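Package: tbsepcea
Title: Decision-Tree Cost-Effectiveness Analysis of Empiric Tuberculosis
    Therapy in HIV-Positive Sepsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic comparison of immediate empiric
    anti-tuberculosis therapy ("treat all") against diagnosis-dependent
    standard of care for HIV-positive patients admitted with sepsis, under
    three tuberculosis diagnostic strategies (urine LAM, sputum Xpert
    MTB/RIF, and their combination). Provides a generic decision-tree
    engine with two-dimensional cost/QALY rollback, Bayesian diagnostic
    branch probabilities (positivity, PPV, NPV), incremental
    cost-effectiveness ratios with dominance handling, one-way (tornado)
    deterministic sensitivity analysis, a patient-level Monte-Carlo
    microsimulation oracle, parameter-set perturbation, a calibration
    harness over the structural unknowns of the model, and YAML/JSON
    parameter file input/output with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
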