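Package: ldgi
Title: Long-Range Linkage Disequilibrium SNP Pairs and LD-Based Gene
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects SNP pairs in strong long-range linkage disequilibrium
    (different chromosomes, or the same chromosome separated by at least one
    recombination hotspot) from phased haplotype panels, annotates each SNP's
    genic context (promoter, UTR, CDS with synonymous/nonsynonymous effect),
    and aggregates annotated pairs into categorized gene-gene interaction
    tables with optional overlays of known protein-protein interaction,
    co-expression, and SNP-trait evidence. Includes a seeded simulator that
    plants SNP pairs at exact target r-squared values together with hotspot
    tracks, gene models and genome sequence, so the whole pipeline is
    testable against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
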