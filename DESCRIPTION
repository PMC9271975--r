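Package: tumeq
Title: Equilibrium Prediction for Immune-Controlled Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Numerical tools for the equilibrium (dormancy) phase of
    immune-controlled tumors described by a coupled size-structured
    growth-division equation and a chemotactic drift-diffusion equation for
    effector immune cells. Computes the leading eigenpair of the discretized
    growth-division operator by inverse power iteration on a shifted
    upper-Hessenberg matrix, solves the stationary radial immune-cell field
    on the unit disk, finds the residual tumor mass whose induced death rate
    balances the Malthusian eigenvalue by bisection, cross-validates the
    prediction against long-time integration of the coupled system, performs
    global sensitivity analysis of the equilibrium mass with a polynomial
    chaos surrogate and pick-freeze Sobol estimators, and generates synthetic
    mouse cohorts with the study's mixed-effects statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    MASS,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
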