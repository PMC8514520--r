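Package: pirnasig
Title: Read-Level Signatures of Ribosome-Guided piRNA Biogenesis
Version: 0.1.0
Authors@R:
    person("pirnasig", "developers", email = "pirnasig@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for detecting ribosome-guided piRNA
    biogenesis on mRNA 3'UTRs from small-RNA, ribosome-profiling, and
    degradome sequencing reads: 5'-end overlap distance spectra with
    Z-scores, the ping-pong 5'-5' overlap statistic, footprint-phasing
    periodograms, nucleotide-bias logos with information content,
    first-nucleotide-matched simulated control reads, region-aware
    abundance quantification (ppm/rpkm), partial-correlation coupling
    tests, and 3'UTR piRNA precursor calling.  A seeded synthetic-data
    generator emulates piRNA, ribosome-protected-fragment, and degradome
    libraries so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    optparse,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
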