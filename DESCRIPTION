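Package: neocreat
Title: Dynamic Serum Creatinine Modelling in Extremely Low Birth Weight
    Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates postnatal serum creatinine dynamics in extremely low
    birth weight (ELBW, <= 1000 g) neonates. Creatinine clearance matures
    after birth following a sigmoid Emax (Hill) function of postnatal age;
    serum concentration follows a one-compartment turnover model with a
    constant endogenous input and a time-varying first-order elimination
    rate. A 3-day ibuprofen course is represented as a constant absolute
    reduction of creatinine clearance while exposed. The package calibrates
    the free maturation parameters to reference concentration tables,
    replicates the resulting treatment-effect tables and trajectory
    figures, generates virtual ELBW cohorts with between-subject
    variability and measurement noise, and runs simulation-estimation
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
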