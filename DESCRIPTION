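Package: amoxkin
Title: Kinetic Modeling and Calibration of Enzymatic Amoxicillin Synthesis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling the kinetically controlled synthesis of
    amoxicillin by immobilized penicillin G acylase in batch and semi-batch
    reactors. Implements two kinetic ODE models of the reaction network
    (synthesis plus parallel ester and amoxicillin hydrolysis), forward
    simulation with a stiff-capable solver, synthetic data generation with
    additive Gaussian noise, parameter estimation by Metropolis-Hastings
    MCMC and by a real-coded genetic algorithm, model selection by relative
    root-mean-squared error, and transfer of batch-calibrated parameters to
    semi-batch prediction with posterior predictive bands.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
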