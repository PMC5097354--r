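Package: crosstalkqc
Title: Quantify and Mitigate Sample Cross-Talk in Dual-Indexed Illumina Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for measuring and removing sample cross-talk (index
    hopping and read misassignment) in dual-indexed Illumina amplicon
    sequencing. Reads synchronized triplets of sequence and index FASTQ
    files, matches index reads against a sample sheet with bcl2fastq-style
    mismatch tolerance, assigns sequence reads to their nearest expected
    amplicon by banded edit distance, classifies every triplet into a
    misassignment taxonomy (correct, wrong i5, wrong i7, wrong sequence,
    multi-step), estimates the number of misassigned reads from
    negative-control index pairs that no sample uses, and sweeps
    index-read quality thresholds to choose a filter that removes
    cross-talk while retaining most reads. A seeded simulator generates
    complete multiplexed runs with ground truth so the whole pipeline is
    testable without sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
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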