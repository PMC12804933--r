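Package: mtbr
Title: Finite-Memory Strategies, Multi-Agent Q-Learning and Evolutionary
    Dynamics for Iterated Two-Player Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying finite-memory strategies in iterated
    two-player matrix games such as the repeated Prisoner's Dilemma. Provides
    a fast repeated-match engine with execution noise, a zoo of benchmark
    strategies (tit-for-tat variants, win-stay-lose-shift, grudge-type
    automata, zero-determinant strategies), the memory-two bilateral
    reciprocity (MTBR) strategy, a tabular multi-agent Q-learning trainer
    for discovering strategies against mentor pools, Fermi-rule imitation
    dynamics on well-mixed, lattice and scale-free populations with
    mutation, and replicator-equation predictions with Monte-Carlo payoff
    matrix estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
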