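Package: esfsim
Title: Microsimulation of Primary-Care Coverage Scenarios and Avoidable Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Municipal-level discrete-time microsimulation of Family Health
    Strategy (ESF) coverage scenarios in Brazil and their consequences for
    mortality from ambulatory care-sensitive conditions (ACSCs). Provides a
    seeded synthetic-cohort generator emulating the statistical structure of
    the Brazilian municipal panel, exponential-trend covariate forecasting
    with national recalibration, four policy coverage scenarios (status quo,
    austerity, austerity with Mais Medicos termination, universal health
    coverage), a fixed-effects log-linear mortality model, a Monte Carlo
    engine propagating baseline (Poisson) and effect-size (log-normal)
    uncertainty, between-municipality and racial inequality metrics
    (concentration index, poverty-quintile rate differences, standardised
    rate ratios), and calibration, validation and sensitivity-analysis
    harnesses.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
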