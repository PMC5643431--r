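Package: vasculomorph
Title: Vascular Morphometry and Morphogenomic Signatures from Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tumor vascular architecture in hematoxylin-and-eosin
    histology tiles with a two-step machine-learning pipeline (endothelial
    nucleus classification followed by pixel-wise vascular-area
    classification), extracts skeleton-based vascular morphometry (fractal
    dimension, lacunarity, Euler-Poincare characteristic, branch and arm
    statistics), selects prognostic vascular features by a survival-driven
    stochastic backward search, and derives a surrogate gene-expression
    signature with elastic-net risk models.  Ships a synthetic-data module
    that renders branched vascular networks as two-stain absorbance images
    with paired ground truth and simulates expression/survival cohorts with
    planted risk structure, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    MASS,
    FNN,
    quadprog,
    cluster,
    sp,
    survival,
    glmnet,
    jsonlite,
    png,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
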