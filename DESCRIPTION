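Package: mybkit
Title: Gene-Family Survey Toolkit for R2R3-MYB Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for genome-wide characterization of
    plant R2R3-MYB transcription factor families: position-weight-matrix
    detection of R2 and R3 MYB repeats, neighbor-joining phylogenies from
    Poisson-corrected protein distances with bootstrap subgrouping,
    detection and classification of tandem and segmental gene duplications,
    Nei-Gojobori (1986) Ka/Ks estimation with molecular-clock dating of
    duplication events, exon/intron structure analysis, ZOOPS EM motif
    discovery, and 2^-ddCt qRT-PCR expression analysis. Includes a
    simulator that generates genomes carrying gene families with known
    duplication history and qPCR plates with planted fold changes, so every
    stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
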