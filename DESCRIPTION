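Package: pbpkeo
Title: Whole-Body PBPK and Intracranial EGFR Occupancy Simulation of
    Osimertinib
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A physiologically based pharmacokinetic (PBPK) model of the
    third-generation EGFR inhibitor osimertinib coupled to a turnover model
    of covalent EGFR engagement in brain tissue. Simulates plasma and
    brain-interstitial concentration-time profiles in virtual patient
    populations, the time-course of intracranial occupancy of four EGFR
    variants (wild type, T790M/L858R, L858R, C797S), local sensitivity
    coefficients, factor sweeps with threshold crossings, dose-regimen
    feasibility under efficacy (occupancy >= 80%) and safety (plasma trough
    < 711 nmol/L) thresholds, and CYP-mediated drug-drug interaction
    scenarios with five perpetrators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
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
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
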