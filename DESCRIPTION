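Package: swlanes
Title: Exact Smith-Waterman Protein Database Search with a Packed-Lane
    SIMD Engine and Heterogeneous Work Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact local alignment search of protein queries against FASTA
    databases using the Smith-Waterman algorithm with affine gap penalties.
    Alignments are computed through an emulated packed-lane saturating-integer
    engine that scores several subject sequences per vector (inter-task
    parallelization), with staged recomputation of alignments whose 8-bit
    scores may have overflowed (16-bit lanes, then unbounded integers), dual
    query-profile lookup structures, and a workload partitioner that splits a
    database between a device-style quad-lane pass and a host-style 16-lane
    pass according to configured compute power. Includes a synthetic protein
    database generator for equal-length and Swiss-Prot-like length
    distributions, NCBI plain-text substitution matrix input with bundled
    BLOSUM62 and BLOSUM50, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
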