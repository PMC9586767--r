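Package: deepdict
Title: Multilayer Dictionary Learning with Atom-Graph Regularization for
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a stack of sparse-coding dictionaries with nonlinear
    activations between layers, a heat-kernel k-nearest-neighbour graph
    Laplacian over the final-layer atoms, a label-consistency prototype
    term, and a jointly trained softmax classifier, for multi-class
    classification of grayscale images such as brain MRI slices.
    Includes K-SVD and orthogonal matching pursuit primitives, an
    accelerated proximal-gradient l1 encoder, stratified
    cross-validation and grid-search protocols, a metric suite
    (confusion matrix, precision, recall, balanced accuracy, F1), and a
    synthetic-data generator that plants a known dictionary stack so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    clue,
    png,
    EBImage,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
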