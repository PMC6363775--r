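Package: pggdyn
Title: Eco-Evolutionary Dynamics of Nonlinear Public Goods Games
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and inference for eco-evolutionary public goods games
    with sigmoidal, frequency-dependent growth rates. Producer (cooperator)
    cells pay a cost to release a shared growth factor whose benefit rises
    nonlinearly with the fraction of producers in an interaction neighborhood
    of n cells. The package provides the coupled-logistic mean-field model and
    its exact stochastic individual-based counterpart (Gillespie direct
    method), equilibrium finding and stability classification, phase diagrams
    over the benefit parameters, saddle-node and transcritical bifurcation
    sweeps with hysteresis protocols, a compartmentalized model with
    fluctuating neighborhood sizes, maximum-likelihood estimation of the
    benefit parameters from cell-competition frequency-change assays, and a
    synthetic-data generator emulating such assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
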