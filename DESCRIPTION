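Package: cbcmux
Title: Multiplexed Amplicon Annotation for Community-Based Culture Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates community-based culture collections (CBC) from
    multiplexed near-full-length 16S rRNA amplicon consensus reads.
    Implements combinatorial plate/row/column barcode demultiplexing
    against anchor oligos, a reliability-based quality-control cascade
    (over-length, chimera, nonspecific and error-prone read removal),
    per-well greedy centroid OTU clustering at 97% identity, naive-Bayes
    k-mer taxonomy with bootstrap confidence, and recovery estimation
    against culture-independent community profiles. Ships a synthetic-run
    simulator with coverage-dependent error classes, chimeras, off-target
    reads and control wells so every stage can be exercised and validated
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
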