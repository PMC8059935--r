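Package: hexspat
Title: Spatially Barcoded Microwell Single-Cell RNA-Seq Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for split-pool combinatorially indexed
    single-cell RNA-seq libraries carrying microwell spatial barcodes.
    Covers hexagonal-array geometry and well maps, barcode parsing and
    UMI-deduplicating demultiplexing into sparse spatial count matrices,
    mixed-species (barnyard) quality control with Lin's concordance
    correlation, EM-based ambient RNA decontamination, distance-weighted
    tumor-proximity scoring on concentric well layers, non-negative matrix
    factorization gene-module discovery with cross-tissue matching, and
    negative-binomial spline tests for proximity-associated differential
    expression. A seeded synthetic-data generator provides ground-truthed
    count matrices, species gradients, ambient contamination, and raw
    FASTQ reads for end-to-end round trips.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Biostrings,
    methods,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
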