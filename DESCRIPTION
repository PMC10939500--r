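Package: craniomorph
Title: Dense-Correspondence Craniofacial Morphometrics with Permutation-Based
    Genotype Effect Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative genotype-to-shape analysis for cohorts of 3D bone
    surfaces: template-based dense surface correspondence (two-phase rigid +
    non-rigid registration), generalized Procrustes alignment, principal
    component reduction, dummy-coded partial least-squares effect estimation
    with Freedman-Lane permutation tests (global and per-vertex), and signed
    normal-displacement effect maps. Includes a synthetic-cohort generator
    with known ground truth for parameter-recovery studies, plus closed-form
    single-SNP fixation-index (FST) estimators and Poisson-statistics
    quantification of droplet-digital PCR allele-specific expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
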