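Package: rdnapoly
Title: Intragenomic rDNA Polymorphism Analysis for Arbuscular Mycorrhizal Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify intragenomic polymorphism among the divergent
    rDNA operon copies carried by arbuscular mycorrhizal fungi (Glomeromycota)
    and to evaluate its consequences for OTU clustering and DNA barcoding.
    Includes a multi-copy rDNA community and HiFi amplicon read simulator, a
    copy-recovery pipeline (primer trimming, dereplication, two-parent chimera
    detection, swarm agglomeration, reference filtering, abundance gating),
    pairwise distances with each-gap/ignore-terminal-gap conventions, per-locus
    distance summaries, OTU threshold sweeps, SNP density profiling from read
    pileups, and barcode-gap statistics with conspecific distance thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    methods,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
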