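Package: mmpsim
Title: Agent-Based Simulation of Magneto-Aerotactic Escape Motility in
    Multicellular Magnetotactic Prokaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation and analysis of the
    magneto-aerotactic "escape motility" of multicellular magnetotactic
    prokaryotes (MMPs) near an oxygenated interface.  Provides a
    point-particle engine (magnetic alignment torque plus an oxygen-gated
    run-reversal process), exact two-state continuous-time Markov chain
    analytics with rate estimators fitted from trajectory data, a
    finite-size squirmer engine with near-field lubrication, steric and
    magnetic interactions near a plane boundary, and the trajectory
    statistics (excursion distances, waiting times, left:right swimmer
    ratios, alignment order parameter, escape-success rates) used to
    characterise the behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
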