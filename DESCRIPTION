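Package: hexalign
Title: Seed-and-Extend Short-Read Alignment with Read
    Non-Redundification and a Floating-Diagonal Banded Smith-Waterman
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Short-read DNA alignment toolkit built around four ideas:
    collapsing duplicate reads in a compressed prefix (Patricia) tree that
    also yields the unique reads in sorted order together with prefix
    cross-similarity coefficients; a direct-addressed 2-bit k-mer index
    over the reference set fronted by a one-bit-per-k-mer presence table
    with over-represented seed masking; a cheap bidirectional fuzzy
    extension that filters accidental seed hits and brackets the alignment
    frame; and a local dynamic-programming aligner restricted to a
    floating, variable-width diagonal band with admissible score-bound
    pruning and linearized band storage. A read simulator generates
    error-free and noisy synthetic read sets with a truth table for
    sensitivity experiments, alignments are written as SAM, and a thin
    command-line interface exposes the simulate/dedup/align steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
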