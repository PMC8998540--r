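Package: matdepsim
Title: Agent-Based Microsimulation of Maternal Depression Under
    Income-Inequality-Reducing Interventions
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the prevalence of depression among expectant mothers
    in an urban Canadian setting as a function of relative household income
    (household income minus the neighbourhood median after-tax income) and
    individual, neighbourhood and social-network covariates.  Provides a
    synthetic cohort generator calibrated to published baseline marginals, a
    logistic risk model with prevalence-threshold calibration, progressive
    income-transfer schedules (minimum-wage floor, child benefits with
    phase-out, a basic-income top-up), agent decisions about social ties
    under eight experimental conditions, a trial engine with
    baseline/follow-up accounting, and significance tests for prevalence
    change.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
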