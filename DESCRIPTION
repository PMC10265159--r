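Package: mtdelscan
Title: Detection and Quantitation of Mitochondrial DNA Deletions from
    Long-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls large mitochondrial DNA deletion mutations from
    nanopore Cas9-targeted (nCATS) long reads aligned to a rotated
    circular reference. Deletions are identified from primary-alignment
    CIGAR strings, from chimeric primary/supplementary alignment pairs,
    and by two-pass local realignment of reads whose aligned span
    disagrees with their length. Includes an nCATS-style read simulator
    with ground-truth deletion tables and SAM fixtures, per-read deletion
    frequency statistics, minimum-size threshold sweeps against donor
    age or ddPCR frequency, minor/major-arc classification, and a
    kernel-density permutation test for comparing breakpoint
    distributions between tissues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
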