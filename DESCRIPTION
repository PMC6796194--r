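Package: piratlas
Title: Small-RNA Biotype Classification, piRNA Cluster Discovery, and
    Ping-Pong Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for ovarian small-RNA sequencing
    analysis in Drosophila: length- and annotation-based biotype
    classification of aligned reads (miRNA, endo-siRNA, piRNA, structural),
    de novo piRNA cluster discovery by a sliding-window read-density scan,
    harmonization of canonical cluster fragments, ping-pong 10-nt 5'-overlap
    signature scanning with an enrichment z-score, first-nucleotide (1U)
    bias matrices, transposable-element and 3'UTR piRNA quantification, and
    miRNA- or spike-in-based library normalization with fold-change and
    Benjamini-Hochberg FDR significance calling. Ships a deterministic
    synthetic-data generator that emulates the statistical structure of
    ovarian small-RNA libraries for ground-truth recovery testing, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
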