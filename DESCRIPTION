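Package: osseofe
Title: Finite-Element Load Transfer and Bone Remodelling Analysis for
    Bone-Anchored Implant Stems
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Parametric hexahedral finite-element pipeline for
    percutaneous bone-anchored (osseointegrated) implant stems in
    residual femurs.  Builds a concentric stem/cement/bone assembly mesh,
    solves linear elasticity under stance load cases with orthotropic
    cortical bone in a cylindrical material frame, computes strain energy
    density (SED) fields, and classifies likely adaptive bone remodelling
    (resorption, homeostasis, apposition) against SED thresholds across
    implant stem stiffnesses.  Includes the validation toolbox used to
    compare model predictions with measurements: Lin's concordance
    correlation, Richardson mesh-convergence analysis, one-at-a-time
    sensitivity summaries, and generators for synthetic strain-gauge and
    digital-image-correlation data with realistic noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
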