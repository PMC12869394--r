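Package: ifsi
Title: Immersed Fluid-Structure Interaction by Fictitious-Domain Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale immersed fluid-structure interaction (FSI) solver for
    cardiovascular biomechanics problems such as heart-valve dynamics. An
    incompressible Navier-Stokes solver with residual-based variational
    multiscale (VMS) stabilization on a fixed background grid is coupled to
    immersed hyperelastic solids through a fictitious-domain / distributed
    Lagrange multiplier constraint collapsed to nodal interpolation (force
    spreading), solved monolithically with generalized-alpha time integration
    and Newton's method. Includes structured mesh generators, a Gmsh MSH
    reader, VTU output, and verification benchmarks: an immersed annulus in
    static equilibrium with an analytic pressure field, idealized open and
    closed valves, an oscillating flexible leaflet, and a free-falling sphere
    with wall-corrected Stokes terminal velocity.
License: MIT
Encoding: UTF-8
Imports: Matrix, methods, Rcpp, jsonlite, yaml, xml2, stats, utils
LinkingTo: Rcpp, RcppArmadillo, RcppEigen
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
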