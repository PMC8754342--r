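Package: morphostates
Title: Unsupervised Discovery of Cell Morphological States from
    Transmitted-Light Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for label-free morphological profiling
    of live cells. Brightfield movies are segmented by predicting a synthetic
    cytoplasm-fluorescence channel with a learned pixel-regression network,
    dead cells and debris are removed by a trained classifier, and each cell
    crop is pose-normalized into a binary mask image and an
    intensity-standardized texture image. Twin variational autoencoders learn
    separate shape and texture latent representations, which are fused by a
    weighted concatenation, clustered into morphological states with Louvain
    community detection, embedded with UMAP, and decoded back into images for
    interpretation. State-transition dynamics are inferred without full cell
    tracking, by validated frame-to-frame pairing of isolated cells and
    row-normalized transition counting. A synthetic-data module generates
    paired brightfield/fluorescence frames, labeled crop populations and
    movies of motile cells switching states under a known Markov matrix, so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    EBImage,
    igraph,
    uwot,
    tiff,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    clue,
    nnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Clustering, SingleCell, Software
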