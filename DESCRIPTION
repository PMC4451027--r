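Package: divlabsim
Title: Adaptive Dynamics and Individual-Based Simulation of Social Division of Labour
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the evolution of heritable task specialisation in groups
    that solve a collective task made of two costly subtasks. Provides the
    analytical adaptive-dynamics machinery (power-law cost trade-off, group
    benefit sharing, selection gradients, singular points, invasion analysis,
    convergence/branching classification) together with a fast individual-based
    evolutionary simulator and batch experiment drivers (branching-frequency
    sweeps, initial-condition basin grids, asymmetric-benefit runs) at
    configurable scale, plus JSON configuration and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
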