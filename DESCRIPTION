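Package: sfgcn
Title: Sequence Feature Graphs and Graph Convolutional Networks for
    Essential Gene Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes DNA sequences as k-mer sequence feature graphs --
    contiguous and gapped k-mer occurrence frequencies as node features,
    consecutive-window co-occurrence counts as edge weights -- and
    classifies the graphs with a graph convolutional network followed by
    one-dimensional convolutional layers and a fully connected softmax
    head, trained by mini-batch gradient descent on class-weighted
    cross-entropy.  Includes FASTA input with stratified train/validation/
    test splitting and stratified k-fold cross-validation, a rank-based
    evaluation panel (sensitivity, specificity, accuracy, precision, F1,
    Matthews correlation, AUC), a Markov-chain synthetic sequence
    generator that plants a higher-order composition signal with matched
    lower-order statistics, and reproducible experiment drivers for
    (k, d) encoder grids and graph-convolution depth ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
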