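Package: siseq
Title: Serial Illumina Sequencing of 16S rRNA Hypervariable Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of serial Illumina sequencing
    (SI-Seq) of bacterial 16S rRNA hypervariable regions. Provides
    structured reference construction by degenerate-primer alignment and
    fragment concatenation (V5::V6a::V7::V6b), a read simulator with mock
    communities and a quality-coupled substitution error model, a
    read-processing front end (dual-barcode demultiplexing, Phred quality
    filtering, orientation resolution), an RDP-style naive Bayes taxonomic
    classifier with bootstrap confidence, calibrated greedy centroid OTU
    clustering with control-derived abundance thresholds, and standard
    community-ecology summaries (rarefaction, Chao1, Bray-Curtis, species
    accumulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    vegan,
    ggplot2,
    generics,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    readr,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
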