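Package: exokin
Title: Kinetic Analysis of DNA Polymerase Proofreading
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pre-steady-state kinetics of proofreading
    DNA polymerases. Builds mass-action kinetic schemes for the competing
    polymerase/exonuclease pathways of a replicative polymerase, integrates
    them with a stiff implicit solver, fits single-turnover quench-flow time
    courses by simulation with locked and floated rate constants, computes
    integrated flux partitioning between competing branches, derives
    thermodynamic parameters (van't Hoff) for intramolecular DNA transfer,
    and quantifies the net contribution of the exonuclease to replication
    fidelity by simulating the fate of a terminal mismatch. Includes a
    synthetic-data generator emulating rapid-quench excision and extension
    experiments and a stochastic (Gillespie) simulation oracle for
    validating the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
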