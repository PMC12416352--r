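Package: eulfsi
Title: Full Eulerian Fluid-Structure Interaction for Deformable Embolic Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-field (full Eulerian) fluid-structure interaction solver for an
    incompressible Newtonian fluid coupled to incompressible Neo-Hookean
    visco-hyperelastic solids on structured Cartesian grids. The solid is captured
    by a geometric volume-of-fluid method with piecewise linear interface
    construction (PLIC) refined by a reconstruction distance function (RDF), and
    its strain state by transport of the volume-fraction-corrected left
    Cauchy-Green tensor. Includes analytic particle-shape constructors with
    surface-area matching, torus deformation analytics (gyration-tensor
    orientation, cross-section ellipse fits, bending angles, projected-circle
    aspect ratios, Q-criterion), and end-to-end scenarios: lid-driven cavity FSI
    verification, forced Hagen-Poiseuille pipe flow, torus transport in a periodic
    pipe, and embolization of surface-area-matched particles in a stenotic pipe.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
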