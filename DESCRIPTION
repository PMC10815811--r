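Package: contactfuse
Title: Contact-Map Protein Embeddings with Sequence Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds fixed-length protein feature vectors from structure and
    sequence and evaluates them with a repeated-split classification
    harness. Structures are read from PDB files; the C-alpha trace yields a
    binary contact map (8 Angstrom threshold) that is reduced with a
    variance-preserving principal-component projection and flattened into a
    structural embedding. Sequences extracted from the same files yield
    k-mer count vectors, and precomputed language-model embeddings can be
    loaded from delimited tables. Embeddings are fused by concatenation and
    assessed with stratified 70/30 splits, a tuning holdout, seven standard
    classifiers, one-vs-rest multiclass metrics, repeated runs, and Welch
    tests between methods. A synthetic-structure generator with
    controllable geometry and sequence motifs makes the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
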