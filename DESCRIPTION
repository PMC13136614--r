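Package: chotwin
Title: Hybrid Digital-Twin Simulation of Fed-Batch CHO Cell Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid mechanistic/data-driven simulation engine for fed-batch
    Chinese hamster ovary (CHO) cell cultures producing monoclonal antibodies.
    Combines Bayesian ensemble estimation of specific metabolic rates from
    concentration time series, a recurrent neural-network growth-rate
    predictor, kinetic ODE models of biomass populations and core ("FLEX")
    metabolites with Nelder-Mead parameter identification, a stepwise
    metabolic-network reduction pipeline, and a PCA-constrained dynamic flux
    balance analysis (PC-dFBA) that couples stoichiometric constraints with
    empirical flux-correlation constraints. An integrated bioreactor simulator
    predicts viable cell density, product titer and metabolite trajectories
    from initial conditions and a feed schedule alone. A synthetic-data
    generator with known ground truth makes the whole pipeline testable
    without access to proprietary process data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    quadprog,
    boot,
    nnet,
    xml2,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
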