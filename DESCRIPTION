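Package: canopyLAI
Title: Leaf Area Index Estimation from Multispectral Canopy Texture
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating crop canopy leaf area index (LAI) from
    six-band multispectral imagery. Implements gray-level co-occurrence
    matrix (GLCM) texture feature extraction over sliding windows,
    classical vegetation indices, exhaustive correlation searches over
    two- and three-feature texture indices, significance screening of
    candidate predictors, and an input-combination by model estimation
    grid (support vector regression, partial least squares regression,
    gradient boosting). A synthetic split-plot scene generator emulates
    a mulching by nitrogen field experiment so the full pipeline can be
    exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    data.table,
    e1071,
    xgboost,
    mixOmics,
    SummarizedExperiment,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImageProcessing, Regression, Software
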