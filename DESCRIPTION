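Package: enhancerkit
Title: Explainable Sequence Models of Enhancer Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and dissects a hybrid convolutional-recurrent neural
    network that classifies 500-bp regulatory regions into topics of
    co-accessible chromatin, in the style used to decode melanoma enhancer
    logic. Provides a synthetic-data generator with known motif ground
    truth, region and sequence handling (BED/FASTA, window augmentation,
    topic labelling, genome tiling), model training with strand-averaged
    prediction, interpretation tools (convolutional filter to PWM
    conversion, per-nucleotide attribution, in silico saturation
    mutagenesis, motif instance localization), enhancer motif-composition
    clustering and positional signal aggregation, and cross-species
    analyses (cis-regulatory module scoring, branch-length-score motif
    conservation, affine-gap ortholog alignment, per-mutation effect
    prediction, and embedding-based enhancer orthology).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
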