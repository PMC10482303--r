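Package: nabres
Title: Structure-Based Prediction of Nucleic Acid-Binding Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA- and RNA-binding residues from protein structure by
    merging a deep learning module and a template-based module. Residue contact
    graphs carry curvature (Ollivier-Ricci, Forman-Ricci), multifractal,
    distance-profile and shape descriptors plus sequence-profile transforms; an
    edge-featured graph attention network and a bank of tree-ensemble template
    classifiers are stacked by a gradient-boosted meta-learner, and predictions
    are smoothed by a random walk with restart on the surface-residue network.
    Ships a synthetic-structure generator so the whole pipeline is exercisable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    nortest,
    randomForest,
    Rcpp,
    stats,
    utils,
    xgboost
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
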