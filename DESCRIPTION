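Package: mrnapkpd
Title: Translational Pharmacokinetic-Pharmacodynamic Modelling for mRNA
    Enzyme Replacement Therapeutics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semimechanistic population pharmacokinetic/pharmacodynamic
    modelling of lipid-nanoparticle-delivered messenger RNA therapeutics,
    motivated by dual PCCA/PCCB mRNA replacement of propionyl-CoA
    carboxylase (PCC) in propionic acidemia.  Implements a linear
    three-compartment mRNA disposition model with allometric interspecies
    scaling, an effect-compartment-driven two-compartment indirect-response
    model for hepatic protein expression, direct sigmoidal maximum-inhibition
    (Imax) models for downstream plasma biomarkers, nonlinear mixed-effects
    estimation by Laplace or adaptive Gauss-Hermite marginalisation with
    M3 censored likelihood for below-quantification observations, simulation
    of study populations in NONMEM-convention long format, visual predictive
    checks, and allometric extrapolation of dose-response to humans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
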