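Package: isomiRsel
Title: Selective Detection of 3'-End miRNA Isoforms by Polyadenylation RT-qPCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and evaluating polyadenylation RT-qPCR
    assays that discriminate 3'-end length variants (isomiRs) of a microRNA
    family. Implements isoform-targeted forward-primer design with the
    4A 3'-extension rule, a sequence-level annealing model that predicts
    primer-by-isomiR cross-amplification classes, the 2^-dCq / 2^-ddCq
    relative-quantification arithmetic, classification of aligned small-RNA
    reads into per-length isomiR counts with RPM and reference-gene
    normalisation, and a seeded simulator of isomiR read sets and Cq tables
    so that every analysis stage can be exercised without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
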