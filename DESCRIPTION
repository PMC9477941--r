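Package: cardiowave
Title: Coupled One-Dimensional Arterial Pulse-Wave and Reduced-Order Cardiac Cavity Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale simulator of heart-vessel interaction. A
    one-dimensional blood-flow solver (visco-elastic Voigt-type tube law,
    second-order finite-volume scheme, RCR Windkessel terminals, bifurcation
    junctions, lumped stenosis element, Bernoulli aortic valve) is
    monolithically coupled to reduced-order cardiac cavity models (time-varying
    elastance and a thick-walled incompressible sphere with a Guccione passive
    law and a phenomenological active-stress transient) through a saddle-point
    volume/pressure formulation solved by Newton iteration at every coupling
    step. Includes fixture generators for single-vessel, stenosed and
    bifurcating-tree networks, analytic inflow waveforms, plain-text network
    and waveform file formats, and a command-line entry point.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
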