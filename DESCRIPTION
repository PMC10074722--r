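Package: hotwave
Title: Wavelet-Feature Prediction of Hot Spots at Protein-DNA Interfaces
Version: 0.1.0
Authors@R: person("hotwave", "developers", email = "hotwave@example.org",
    role = c("aut", "cre"))
Description: Predicts hot-spot residues at protein-DNA binding interfaces
    from per-residue structural descriptors. Groups of solvent-accessibility
    and secondary-structure features are treated as short digital signals and
    summarised by multilevel Haar discrete wavelet transform and level-3
    wavelet packet transform energies and entropies, expanding 43 traditional
    descriptors to a 175-dimensional feature vector. Class imbalance is
    handled by SMOTE interpolation, features are selected by a minimum
    redundancy maximum relevance ranking followed by sequential forward
    selection under cross-validated AUC, and classification uses a
    gradient-boosted decision-tree ensemble implemented in C++. Includes a
    synthetic data generator, leakage-safe stratified cross-validation, the
    standard binary-classification metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
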