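Package: shatterscan
Title: Detection and Classification of Shattered Chromosomes from Short-Read Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of catastrophic chromosome restructuring (chromothripsis
    and chromoanasynthesis) arising during centromere-mediated genome
    elimination in hybrid plants. Converts short-read alignments into binned
    dosage profiles scaled to a diploid background of 2, segments them into
    integer copy states, and classifies chromosomes as euploid, numerical,
    truncated or shattered; assigns parental origin of copy-number variant
    regions from hybrid-diagnostic SNPs; reconstructs breakpoint junctions by
    local assembly and split alignment, classifying each as microhomology,
    blunt or insertion and scoring inversion orientation; tests enrichment of
    genomic features in windows around breakpoints with a permutation null;
    and computes exact contingency statistics for cross-outcome tables. A
    built-in simulator plants parental genomes, a shattered chromosome with a
    machine-readable truth set, and error-free reads, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
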