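Package: adtcount
Title: Antibody-Derived Tag Counting for ASAP-seq and CITE-seq Data
Version: 0.1.0
Authors@R:
    person("adtcount", "developers", email = "adtcount@example.org",
           role = c("aut", "cre"))
Description: Transforms paired FASTQ reads from antibody-derived tag (ADT)
    experiments such as ASAP-seq and CITE-seq into a sparse cell-by-marker
    count matrix. One read of each pair carries the cell barcode, the other
    the antibody-conjugated oligo and the unique molecular identifier (UMI).
    Cell barcodes are matched against a whitelist by Hamming distance, tag
    oligos against a reference panel by a normalized edit-distance ratio,
    reads matching multiple references are filtered out, PCR duplicates are
    collapsed by exact or near-match UMI deduplication, and the result is
    written as a CellRanger-style MatrixMarket triplet. A seeded synthetic
    read generator with full ground truth supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    graphics,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
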