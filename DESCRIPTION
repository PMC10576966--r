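Package: TopoSumo
Title: Topological Feature Encoding for Sumoylation Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Persistent-homology encoding of lysine-centered peptide
    structures for predicting protein sumoylation sites. Computes
    Vietoris-Rips and Alpha filtration barcodes of element-labeled
    heavy-atom point clouds, including element-specific variants, and
    vectorizes them by death-time binning and barcode statistics into a
    356-dimensional topological feature vector per site. Includes F-score
    feature ranking, NearMiss undersampling, gradient-boosting, random
    forest and support-vector classifiers with cross-validated and
    independent-set evaluation, and a deterministic synthetic-structure
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    e1071,
    xgboost,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
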