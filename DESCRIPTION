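Package: fcpminer
Title: Index-Based Mining of Frequent Contiguous Patterns in Biological
    Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines all frequent contiguous patterns (conserved motifs) from a
    database of DNA, RNA or protein sequences. A single scan builds, for every
    candidate pattern, a per-sequence occurrence-position table and a sorted
    index of the sequences containing it; support is counted directly from the
    index, and patterns are grown level-by-level through an adjacency join of
    equal-length patterns with an intersection-cardinality prune. Includes an
    independent brute-force enumeration oracle for validation, a reproducible
    synthetic sequence generator with planted motifs, FASTA and plain-text
    input, TSV/JSON reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
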