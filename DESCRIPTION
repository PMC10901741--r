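Package: tetrap
Title: Detection of Transposable-Element Gene Traps from RBP Peaks and RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis suite for detecting transposable-element (TE) exonization,
    premature transcription termination and alternative polyadenylation from
    RNA-binding-protein (RBP) peak sets and RNA-seq count data. Provides strand-aware
    interval algebra and priority fragmentation of gene models, merging and host-gene
    assignment of RBP peaks, strand-separated TE family enrichment, an in-package
    negative-binomial differential expression and relative-usage engine, the
    pre-/post-peak gene fragmentation pipeline for early-termination calls,
    splice-junction filtering with an intron-centric splicing index and a stringent
    tissue-panel filter chain, long-read 3'-end collapse with differential
    polyadenylation calls, peak-space clustering reports, and a seed-deterministic
    synthetic-data generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
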