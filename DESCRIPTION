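Package: fluxness
Title: Variational Non-Equilibrium Steady States of Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing non-equilibrium steady states (NESS) of chemical
    reaction networks through a variational principle: stationary reaction fluxes
    minimize a Hopfield-like quadratic function H of the fluxes, built from Hebbian
    couplings between reactions that share chemical species. Provides a plain-text
    network format with reader, writer and validator; construction and evaluation of
    the coupling system and of H; a stochastic resource-allocation dynamics whose
    time-averaged fluxes realize the minimization, with classification of reactions
    into bidirectional and frozen (unidirectional) ones; random-network ensembles
    exhibiting an ergodicity-breaking phase transition; linear-stability analysis
    against the Marchenko-Pastur spectral edge; direct box-constrained minimization
    of H, flux-norm minimization for loop removal and a thermodynamic-feasibility
    certificate via the Gordan alternative; Gibbs energies, entropy production and
    perturbation free energies; and a reduced human red-blood-cell case study of
    glucose partitioning between glycolysis and the pentose phosphate pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
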