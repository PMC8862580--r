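Package: svpair
Title: Structural Variant, Transposable Element, and Chromatin Compartment
    Comparison of Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two related genome assemblies (e.g. two ecotypes of one
    plant species) end to end: structural variants are called from the gap
    signatures between unique whole-genome-alignment anchors and classified
    into insertion, deletion, repeat and tandem copy-number classes;
    transposable-element insertions are detected by alignment-gap and
    annotation-coverage rules; A/B chromatin compartments are called per
    chromosome from the leading eigenvector of the observed/expected
    correlation of a binned Hi-C contact matrix; syntenic blocks are chained
    from gene-anchor pairs and used to classify compartment switches between
    the genomes; short-read SV call sets are merged and filtered and their
    concordance with the alignment-based presence/absence variants is
    measured. A seeded simulator generates diverged genome pairs with planted
    variants, rearrangements and plaid Hi-C contact structure, plus complete
    truth tables, so every step is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
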