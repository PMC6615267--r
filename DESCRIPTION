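Package: oae
Title: Orthogonality-Constrained Poisson Autoencoders for Interpreting
    Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits shallow autoencoder neural networks directly to raw
    single-cell RNA-seq counts using a Poisson negative log-likelihood
    loss with a soft orthogonality penalty on the final encoder weight
    matrix, so that units of the low-dimensional representation layer
    disentangle into interpretable biological modules.  Guided
    backpropagation saliency maps attribute each hidden unit to input
    genes, and gene-set (GMT) impact scores summarise which pathways or
    signatures each unit models, for a whole dataset or as a contrast
    between two groups of cells.  Includes a synthetic count simulator
    with planted gene modules for validation, clustering-agreement
    evaluation (k-means, normalized mutual information), FACS-style
    quantile gating, Hungarian matching of gene sets to hidden units,
    and UMAP embedding of the learned representation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    methods,
    jsonlite,
    clue,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
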