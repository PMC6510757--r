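Package: stemloopr
Title: Recognition of 3'-End Stem-Loops of Retrotransposon-Like Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects approximate stem-loop (inverted-repeat) structures in DNA
    sequences under explicit constraints on stem length, loop length, mismatches
    and bulges; selects stem-loops in terminal 50-bp windows; builds the negative
    class by Altschul-Erikson dinucleotide-preserving shuffling; encodes instances
    as k-mer frequency vectors or as 134-dimensional structure vectors combining
    dinucleotide physico-chemical stem properties with one-hot loop and bulge
    blocks; and trains and evaluates Random-Forest classifiers with cross-validated
    metrics, feature-importance rankings and cross-set recognition rates. Includes
    a seeded synthetic-sequence generator with planted hairpins so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
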