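Package: qvoter
Title: Monte Carlo and Mean-Field Analysis of the q-Voter Model with
    Independence
Version: 1.0.0
Authors@R: person("Quantitative", "Dynamics Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Seeded agent-based simulation of binary opinion/adoption
    dynamics under the q-voter rule with independence, in two microscopic
    variants: a quenched 'person' model in which a fixed fraction p of
    agents is permanently independent, and an annealed 'situation' model
    in which every agent acts independently with probability p at each
    update. Provides complete-graph and Barabasi-Albert topologies, the
    mean-field evolution equations for both variants with stationary
    states, bifurcation diagrams and critical independence levels, ensemble
    experiments (phase-diagram sweeps, Monte Carlo versus mean-field
    comparison, agent-by-time occupancy rasters), and a command-line
    interface with deterministic, provenance-tracked outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
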