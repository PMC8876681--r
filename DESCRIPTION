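Package: imgg
Title: Multi-Batch Single-Cell Integration via Connected Graphs and a WGAN-GP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Corrects batch effects in single-cell RNA-seq expression
    matrices by repeatedly finding cross-batch mutual-nearest-neighbor
    (MNN) cell pairs in PCA space, assembling cross-batch similar-cell
    connected graphs (closed-loop, transmitting and weak-transmitting
    rules), synthesizing an intermediate batch per cohort of similar
    cells (elementwise Mean, Max or Min), and training a Wasserstein GAN
    with gradient penalty whose generator maps every cell onto the
    intermediate batch. Returns a corrected gene-expression matrix and
    batch-mixing / cell-type-purity evaluation metrics (silhouette,
    adjusted Rand index, local inverse Simpson's index). Includes a
    negative-binomial multi-batch simulator so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    cluster,
    mclust,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
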