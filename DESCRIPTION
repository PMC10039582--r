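Package: ossam
Title: Statistical Shape and Appearance Modelling of the Femur with 2D-3D
    Reconstruction from Simulated Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to build statistical shape and appearance models (SSAM) of
    the femur from corresponded surface and tetrahedral meshes, simulate planar
    radiographs (digitally reconstructed radiographs, DRRs) with distal bone
    defects, recover three-dimensional bone shape from one or two projections
    by bound-constrained optimisation of PCA mode weights against contour- or
    intensity-based image metrics, and score reconstructions with surface
    errors (RMSE, Hausdorff) and clinically used anatomical measures (bow,
    neck, diaphyseal-condylar and version angles, head radius). A seeded
    parametric femur phantom generator provides populations with known
    ground-truth geometry so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    withr,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
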