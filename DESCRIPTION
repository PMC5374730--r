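Package: bsrealign
Title: Hinted Windowed Re-Alignment and Methylation Calling for
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome DNA methylation calling from location-hinted,
    bisulfite-treated read pairs. Each read carries an approximate genomic
    coordinate; the package re-aligns it inside a +/-1000 bp reference
    window with a Smith-Waterman local aligner whose substitution function
    is bisulfite-aware and asymmetric (read T against reference C, or read
    A against reference G, scores as a match) and which records the best
    source direction per cell so traceback needs no branch re-evaluation.
    Read groups pair a bisulfite-treated end with an untreated anchor end;
    groups are threshold-filtered, PCR duplicates are collapsed to the
    best-scoring observation, and per-cytosine methylated/unmethylated
    counts are aggregated genome-wide into CX-style and bedGraph reports.
    Chunked input and contiguous group partitioning give a parallel
    execution mode whose output is byte-identical to serial execution.
    A seeded simulator generates reference, methylation states, and hinted
    read pairs with a ground-truth table for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
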