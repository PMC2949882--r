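Package: brainshift
Title: Biomechanical Brain-Shift Models with Landmark-Guided Parameter Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element models of brain deformation after craniotomy for
    image-guided neurosurgery: a small-strain linear elastic ("mechanical")
    model and a stationary polynomial hyperelastic model in the invariants of
    the left Cauchy-Green tensor, both on 4-node tetrahedral meshes with a
    craniotomy boundary-condition scheme (fixed surface, traction-free exposed
    rim, force-loaded exposed center). Material and load parameters are
    estimated from sparse landmark displacements by Nelder-Mead minimization
    of the summed landmark distance. Includes a deterministic sphere-phantom
    generator, an inverse-crime recovery experiment driver with per-axis error
    reports, and legacy-VTK mesh input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
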