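Package: sprintfatigue
Title: Compartmental Muscle Fatigue Modelling from Wearable Speed Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Three-compartment motor-unit fatigue model for field sports,
    driven by a demanded-activation profile with asymmetric activation and
    deactivation rates. Provides fixed-step Euler simulation of active,
    fatigued and available energy compartments, preprocessing of 18 Hz
    wearable speed traces (1 s smoothing, kinetic-energy conversion),
    construction of demanded-activation step profiles for repeated-sprint
    tests and match play, particle swarm calibration of per-athlete rate
    parameters within physiological bounds, and seeded synthetic session
    generators so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
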