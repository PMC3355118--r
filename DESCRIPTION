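Package: warpgauge
Title: Quantifying Geometric Distortion Between Paired MR Acquisitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring geometric distortion between two MR
    acquisitions of the same brain, such as a clinical 1.5 T scan and an
    ultra-high-field 7 T scan used for surgical targeting. Provides a
    digital phantom simulator with known ground-truth distortion, bias
    correction and brain extraction, staged mutual-information affine
    registration (coarse rotational search, 6-DOF refinement, 12-DOF
    affine), decomposition of affine transforms into scale, skew and
    volume-change distortion metrics, landmark-based target registration
    error statistics, and piecewise regional registration producing a
    spatial distortion map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
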