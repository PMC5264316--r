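Package: poets
Title: Pareto Optimal Ensemble Technique for Multiobjective Model Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates ensembles of model parameters on or near the optimal
    trade-off surface between conflicting training objectives using
    multiobjective simulated annealing with Fonseca-Fleming Pareto ranking.
    Supports box bounds, inequality constraints via a penalty method, hybrid
    single-objective local refinement, and multistart search. Ships a suite
    of constrained algebraic benchmark problems and a proof-of-concept
    hybrid cybernetic model of a small metabolic network, including
    elementary flux mode enumeration, synthetic conflicting training data
    generation, and ensemble trajectory summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
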