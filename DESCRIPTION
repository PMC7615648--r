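Package: tterm
Title: Genome-Wide Analysis of DNA-Encoded RNA Polymerase II Termination at T-Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterise sites of spontaneous,
    DNA-encoded RNA polymerase II transcription termination at thymidine
    homopolymer tracts in compact genomes such as Saccharomyces cerevisiae.
    Implements strand-aware homopolymer-tract scanning over extended open
    reading frames with gene-assignment discard rules, strand-specific
    per-base 3'-end read coverage with counts-per-million scaling and
    replicate QC, a pseudocount-ratio island caller for spontaneous
    termination sites, poly(A)-site filtering and terminator-tract
    assignment, metagene signal matrices with outlier blacklisting, k-mer
    motif enrichment of termination-site flanks, single-molecule FRET
    trajectory idealization and post-synchronization histograms, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Rsamtools,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
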