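Package: lexiphylo
Title: Phylogenetic Inference from Phonetically Transcribed Word Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phylogenetic inference in historical linguistics from
    short core-vocabulary word lists transcribed in the 41-symbol ASJP
    sound-class alphabet. Implements pointwise mutual information (PMI)
    substitution-score estimation by iterative weighted alignment, calibrated
    pairwise language distances, supervised cognate clustering (SVM with
    Platt scaling followed by label propagation), extraction of binary
    cognate-class and soundclass-concept character matrices, BIONJ tree
    building and rooting, and evaluation statistics (B-cubed scores,
    generalized quartet distance, Mantel correlograms, and a punctuated
    evolution test based on phylogenetic generalized least squares). A
    synthetic word-list simulator with known ground truth supports testing
    and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    phangorn,
    e1071,
    vegan,
    geosphere,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
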