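Package: memtax
Title: Hierarchically Labeled Suffix-Array Indexing for Functional Read
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a generalized suffix array over a reference sequence
    database whose records are annotated with nodes of a functional
    taxonomy (for example a four-level enzyme-code hierarchy), augments it
    with a per-suffix label array and a constant-time range
    lowest-common-ancestor structure, and classifies sequencing reads by
    the lowest taxonomic unit (LTU) of their longest maximal exact match
    (MEM). Includes six-frame translation of nucleotide reads against
    amino-acid databases, hierarchical level profiles, a
    substitution-error read simulator with ground truth, and a four-way
    accuracy evaluation (correct / ancestor / root / incorrect).
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
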