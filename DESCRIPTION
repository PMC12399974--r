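Package: etaplan
Title: Traction Biomechanics and Patient Stratification for Endoscopic
    Thyroidectomy via the Areola Approach
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale fluid-structure-interaction pipeline for preoperative
    planning of total endoscopic thyroidectomy via the areola approach (ETA).
    Builds parametric tissue-artery geometries with tagged tetrahedral meshes,
    solves static Neo-Hookean soft-tissue mechanics under instrument traction
    with a nodal-pressure anti-locking formulation, computes steady laminar
    blood flow in the innominate-artery lumen with a stabilized equal-order
    finite-element scheme, couples the two in a staggered fashion, applies the
    deformation-versus-DD3 level-VII clearance rule to CT landmark distances,
    and reproduces the cohort statistics (Welch ANOVA, chi-square, Pearson)
    on synthetic patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
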