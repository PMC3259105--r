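Package: piRNAkit
Title: Small-RNA Analysis of piRNA Clusters, Ping-Pong Signatures and
    Sequence-Pool Diversity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing Piwi-interacting RNA (piRNA) populations
    from small RNA-seq libraries: adapter stripping and contaminant removal,
    size-class partitioning, full-length ungapped genome mapping with
    uniqueness classification, piRNA-cluster discovery by windowed genome
    scan with a random-interval transposon-content null model, ping-pong
    amplification signature statistics (10-nt 5' overlaps, U1/A10 bias),
    transposable-element and gene target tabulation, gene piRNA-density
    ranking, transgene-derived piRNA detection, and Lincoln-Petersen
    capture-recapture estimation of piRNA sequence-pool diversity. Includes
    a seeded synthetic-data generator that emulates the statistical
    structure of mosquito small-RNA libraries for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, Alignment, Coverage, Epigenetics
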