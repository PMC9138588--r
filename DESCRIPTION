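Package: dtiforge
Title: Drug-Target Interaction Prediction from Protein Evolutionary
    Profiles and Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of drug-target interactions (DTIs).
    Proteins are characterised by PSI-BLAST position-specific scoring
    matrices (PSSMs) reduced to a fixed 20x20 cross-product matrix, drugs by
    881-bit PubChem substructure fingerprints decoded from their Base64
    transport encoding.  A small convolutional neural network trained by
    full-batch gradient descent extracts a low-dimensional protein
    representation, which is fused with the fingerprint bits and classified
    by an extreme learning machine whose output weights are the minimum-norm
    least-squares solution.  Includes balanced negative-set construction for
    bipartite interaction networks, five-fold cross-validation with the
    standard confusion-matrix metric suite and trapezoidal ROC/AUC,
    a 2D-PCA ablation descriptor, candidate ranking for unknown pairs, and
    planted-signal synthetic data generators so the whole pipeline runs and
    tests without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
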