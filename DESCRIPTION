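Package: hemofem
Title: Finite-Element Simulation of Hybrid-Nanofluid Blood Flow Through a
    Ruptured Sidewall Aneurysm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transient incompressible Navier-Stokes and advection-diffusion
    heat transport of a blood-based gold/silver hybrid nanofluid through a
    straight vessel carrying a ruptured sidewall dilatation (aneurysm sac with
    an apex orifice). Effective suspension properties follow the two-step
    Brinkman viscosity and two-step Maxwell conductivity mixture laws.
    Includes a parametric vessel/sac geometry generator with graded
    triangular meshing, an inf-sup stable Taylor-Hood (P2/P1) solver in
    planar and axisymmetric modes with traction outlets and backflow
    suppression, an SUPG-stabilised energy equation with viscous dissipation,
    verification scenarios (Poiseuille limits, manufactured solutions,
    conservation audits), and post-processing to extremes tables, line
    samples, Gmsh MSH and legacy VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    generics,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
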