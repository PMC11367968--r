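Package: stenoflow
Title: Desk-Scale Haemodynamics of Extrinsic LVAD Outflow-Graft Stenosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric stenosed-graft geometries for the HeartMate 3 outflow
    conduit, virtual stepwise stenosis augmentation, a desk-scale unsteady
    incompressible Navier-Stokes solver (staggered-grid projection method,
    axisymmetric or planar), and the haemodynamic post-processing used to
    grade extrinsic outflow-graft obstruction: plane-averaged pressure
    profiles and pressure gradients, peak velocity, Reynolds-decomposed
    velocity fluctuations and turbulent kinetic energy, radiological
    percent-reduction arithmetic, and severity-by-flow sweeps with Pearson
    correlation panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    ggplot2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
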