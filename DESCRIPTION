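Package: cellmixr
Title: Neural-Network Cell-Type Deconvolution with Transfer Learning and
    Integrated-Gradient Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates cell-type fractions from bulk and spatial
    transcriptomics profiles with a dense neural network trained on
    pseudobulk mixtures simulated from annotated single-cell data.
    Provides the full stack: synthetic single-cell corpora with planted
    marker structure, quality-control filtering and per-input
    normalization, pseudobulk mixture simulation with known fractions,
    a configurable ELU network with masked mean-squared-error loss and
    corruption-based regularization, belief propagation of predicted
    fractions over a cell-type ontology, a reference-guided transfer
    deconvolver (network embeddings, non-negative matrix factorization,
    two-batch alignment, bagged linear nu-support-vector regression),
    integrated-gradient feature attribution, and evaluation utilities
    based on Lin's concordance correlation coefficient, including
    sensitivity sweeps and spatial downsampling with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    igraph,
    jsonlite,
    pracma,
    rhdf5,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
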