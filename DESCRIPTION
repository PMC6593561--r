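Package: mitescape
Title: Classification, Amplification Dating, and Genomic Impact of MITEs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-annotation analysis of miniature inverted-repeat
    transposable elements (MITEs) in plant genomes. Groups annotated MITE
    copies into families under the 80-80-80 rule, detects terminal inverted
    repeats and target-site duplications, assigns superfamilies
    (Tc1/Mariner, PIF/Harbinger, hAT, Mutator), dates family amplification
    bursts from the modality of pairwise nucleotide diversity, builds
    Kimura two-parameter neighbor-joining trees, partitions scaffolds into
    gene-associated and intergenic space, profiles MITE-derived small RNAs
    by relative position, detects the four basic alternative-splicing modes
    and their MITE associations, and simulates genomes with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    broom,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
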