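Package: svunify
Title: Size-Aware Filtering, Merging and Benchmarking of Structural Variant Deletion Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating deletion calls from multiple structural
    variant callers into a unified call set, and for benchmarking call sets
    against a truth set. Implements per-caller size-range filtering,
    reciprocal-overlap duplicate removal prioritised by per-size precision
    priors, and a margin-extended Jaccard quality metric that yields
    size-stratified precision, recall and F-measure. Includes a seeded
    simulator that injects deletions and insertions into a reference genome
    and emits paired-end reads with a configurable insert-size and
    substitution-error model, and a caller emulator with controlled per-size
    recall, false-positive rate and breakpoint jitter for end-to-end testing
    without external callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
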