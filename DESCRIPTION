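Package: caresynergy
Title: Evolutionary Game Dynamics of Integrated Health and Social Care
    Cooperation
Version: 0.1.0
Authors@R:
    person("caresynergy", "developers", email = "caresynergy@example.org",
           role = c("aut", "cre"))
Description: Tools for a two-population asymmetric evolutionary game between
    health care organizations and elderly social care organizations deciding
    whether to cooperate on integrated care provision. Implements the payoff
    matrix, expected payoffs and replicator dynamics of the game; locates the
    five local equilibria and classifies their stability from the Jacobian
    determinant and trace; maps parameter sets to care-model regimes and
    stability scenarios; computes the bilateral-cooperation basin area and its
    parameter sensitivities; integrates the replicator system with an adaptive
    Runge-Kutta core; and reproduces the standard parameter and
    initial-condition sweep experiments, including flip-threshold extraction.
    A command-line interface exposes analysis, simulation, sensitivity and
    sweep subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
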