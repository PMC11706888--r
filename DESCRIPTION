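Package: cellchain
Title: Mechanical Relaxation of Cell Chains on Curved Interfaces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates overdamped chains of mechanically interacting cells
    arranged along an arbitrary smooth planar curve, using either straight
    (chord) springs or curved (arc-following) springs, and solves the
    nonlinear-diffusion continuum limit of these models. Provides arc-length
    reparametrisation of parametric curves, three spring restoring-force laws
    with their cell-level scalings and continuum diffusivities, stress-free
    rest-length solvers, tangential and curvature-induced normal stress
    (surface tension) profiles, relaxation-spectrum analysis of the linearised
    dynamics, and empirical discrete-to-continuum convergence-order
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
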