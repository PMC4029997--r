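Package: adaptrex
Title: Adaptive Temperature Replica Exchange with Self-Guided Langevin Dynamics
Version: 0.1.0
Authors@R:
    person("adaptrex", "maintainers", email = "adaptrex@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for temperature replica-exchange
    (parallel tempering) molecular simulations with dynamically adapted
    temperature ladders. Builds static geometric ladders, performs Metropolis
    temperature swaps with cold/hot walker labeling and round-trip accounting,
    and re-places client temperatures from fraction-cold feedback statistics
    under a geometric spacing constraint. Includes a self-guided Langevin
    dynamics (SGLD) integrator, analytic and Go-type bead energy models with
    decoy generation, structural refinement metrics (fraction of native
    contacts, Kabsch RMSD), and rank-order aggregation analytics for
    refinement score tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
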