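Package: lamellar
Title: Micromechanical Prediction of Indentation Moduli in Lamellar Bone
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Site-matched prediction of nanoindentation moduli in lamellar
    bone from quantitative backscattered-electron (qBEI) mineral maps and
    quantitative polarized-light (qPLM) collagen fibril-angle maps.
    Implements the calcium-to-mineral volume fraction calibration chain, a
    three-level Mori-Tanaka fibril-array homogenization yielding a
    transversely isotropic stiffness tensor, virtual indentation of an
    anisotropic elastic half-space along an arbitrary direction via angular
    integration of the Barnett-Lothe surface Green's function, rigid
    registration of imaging modalities with disk-averaged covariate
    extraction per indent, a seeded synthetic-cohort generator with known
    ground truth, and cohort statistics including a Monte Carlo sensitivity
    study of the fibril-array parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
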