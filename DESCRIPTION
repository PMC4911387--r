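Package: levotap
Title: Levodopa Kinetic-Dynamic Modelling of Finger Tapping in Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a two-compartment model of oral levodopa plasma
    pharmacokinetics with a brain effect compartment, a Hill
    concentration-effect law and a firing-rate basal ganglia network with
    winner-takes-all action selection, to simulate the alternate finger
    tapping task over a four-hour levodopa test. Provides Nelder-Mead
    fitting of the plasma model, grid-search assistance for the effect
    parameters, clinical response metrics (latency, duration,
    stable/wearing-off classification) and a seeded synthetic-patient
    generator reproducing the clinical sampling schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
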