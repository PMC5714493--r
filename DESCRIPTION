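Package: gasplice
Title: Discovery and Classification of Noncanonical GA/GG Intron Donor
    Splice Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering splice junctions from junction-spanning
    RNA reads by anchored spliced alignment under configurable donor
    acceptance rules (GT-only, GY, G-any, any), classifying introns by
    donor and acceptor dinucleotide, intron phase and exon-end context,
    building position frequency matrices and information-content profiles
    of splice-site windows, and mapping intron positions and phases onto
    protein multiple alignments to label introns as shared or
    idiosyncratic across species. Includes a synthetic genome, gene-model
    and read simulator with deterministic quota planting of donor classes
    so that the whole pipeline is testable without external data. The
    motivating biology is the unusually high frequency (10-12%) of
    noncanonical GA and GG 5' donor splice sites in the copepod
    Eurytemora affinis, which defeats standard spliced aligners that
    require GT or GC donors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
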