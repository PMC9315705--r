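Package: plastmarker
Title: Comparative Plastome Analysis and Species-Diagnostic Marker Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of near-identical chloroplast
    genomes: detection of the quadripartite LSC/IRb/SSC/IRa architecture,
    MISA-style microsatellite (SSR) scanning, collinear multiple alignment
    with SNP/InDel calling and region classification, sliding-window
    nucleotide diversity (Pi), neighbor-joining phylogeny from shared
    single-copy protein-coding genes, and the design and in-silico
    validation (PCR plus restriction digestion) of species-diagnostic
    InDel and dCAPS markers. Includes a seeded plastome-evolution
    simulator with machine-readable ground truth so that every stage of
    the pipeline can be tested at desk scale without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
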