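Package: erkltp
Title: Stochastic Simulation of ERK Activation Pathways During L-LTP Induction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-compartment stochastic modelling of the signalling network
    that couples calcium, cAMP and Gi beta-gamma inputs to ERK activation in
    dendritic spines during induction of late-phase long-term potentiation.
    Provides a mass-action reaction-network container with knockout and
    quantity-scaling transforms, an exact Gillespie simulator with an adaptive
    tau-leap accelerator and a deterministic ODE oracle, stimulation protocols
    (single pulses, 100 Hz tetanic trains at massed and spaced intertrain
    intervals, file-based input time series), and the downstream statistical
    stage: area-under-curve summaries, linear/logarithmic/Hill dose-response
    model selection by adjusted R-squared and AIC, combination-versus-summation
    ANCOVA synergy tests, temporal-sensitivity summaries, and random-forest
    ranking of parameter-perturbation robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    randomForest,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
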