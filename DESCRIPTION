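Package: leukoflow
Title: Coupled Hemodynamics and Leukocyte Adhesion in Stenotic Arteries
Version: 0.1.0
Authors@R:
    person("leukoflow", "developers", email = "leukoflow@example.org",
           role = c("aut", "cre"))
Description: Simulates pulsatile incompressible blood flow in stenotic
    artery geometries on a Cartesian staggered grid with the lumen wall
    represented by an immersed boundary, transports leukocyte
    concentration with a wall-shear-stress-thresholded adhesion sink,
    and correlates predicted adhesion profiles with baseline to
    follow-up lumen-area change. Includes idealized stenosis and
    contour-frame (IVUS-style) geometry construction, wall shear stress
    extraction with azimuthal and temporal averaging, a synthetic study
    generator emulating catheter-pullback lumen contours, and
    command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
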