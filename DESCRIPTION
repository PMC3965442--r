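Package: hemocfd
Title: Axisymmetric Weakly-Compressible Blood Flow and Hemolysis Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Finite-difference simulation of laminar blood flow through
    axisymmetric conduits such as the idealized FDA benchmark nozzle, using a
    weakly-compressible formulation of the Navier-Stokes equations with a
    Cole (Tait) equation of state and a reduced artificial sound speed.
    Supports Newtonian, Carreau-Yasuda and Casson (low-shear cutoff) blood
    rheology. Mechanical blood damage (hemolysis) is quantified with the
    Giersiepen power-law model through three routes: integration of the
    linearized damage rate along pathlines, an Eulerian linear-damage
    transport field co-evolved with the flow, and a closed-form axisymmetric
    lower bound based on a local Poiseuille approximation. Physiological
    indicators (mass-flow conservation metric, centerline pressure drop,
    simplified Bernoulli estimate, shear-stress and wall-shear-stress
    profiles, normalized index of hemolysis) are computed from steady
    solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
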