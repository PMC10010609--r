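Package: rootflow
Title: Water and Solute Transport Modelling on Root System Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A functional-structural model of coupled water and solute
    transport in branched root systems. Root architectures are discretized
    into millimetre-scale cylindrical elementary volumes on a tree graph;
    radial water exchange follows a composite hydrostatic-osmotic driving
    force, axial sap flow follows a Hagen-Poiseuille law with a
    distance-to-tip dependent conductance profile, and xylem solutes
    (including a non-permeant osmoticum such as PEG 8000 entering through
    cut xylem faces) are advected with active uptake and passive leak.
    The package simulates pressure-chamber protocols (pressure-flow sweeps,
    spontaneous exudation, and progressive cut-and-flow experiments) and
    estimates radial hydraulic conductivity, the axial conductance profile,
    active solute uptake rate, and solute permeability by staged nonlinear
    least squares. An analytic two-compartment osmometer solution of the
    same closure serves as a solver oracle and for model-bias comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
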