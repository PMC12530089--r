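Package: sigrow
Title: Row-Based Storage, Indexing and Acquisition Simulation for Raw
    Nanopore Signal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a row-based file format for raw nanopore current
    signal in two dialects (a human-readable tab-delimited ASCII variant
    and a length-prefixed binary variant), lossless signal compression by
    a zigzag-delta transform followed by StreamVByte-style variable-byte
    packing (2-byte and 4-byte variants) with optional zlib or zstd record
    compression, a read-ID index sidecar for single-seek random access, a
    minimal column-oriented chunked comparator format with index-free
    "walker" retrieval, a read-benchmark harness with per-read signal-sum
    digests, and a real-time data-acquisition simulator using direct and
    two-pass (temporary file then merge) writing with deadline-based
    warning accounting and capacity search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
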