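Package: selextract
Title: Cell-SELEX Sequencing Analysis: Flank-Validated Insert Extraction,
    Read Collapse, Enrichment and Candidate Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for massively parallel sequencing of SELEX
    (Systematic Evolution of Ligands by Exponential Enrichment) aptamer
    selection pools. Reads paired-end FASTQ files from sequenced selection
    rounds, locates the library's constant flanking regions in each read
    (either strand, with an optional Hamming mismatch tolerance), enforces
    an insert length window around the randomized-region design length,
    strips the flanks and classifies every read with an explicit verdict.
    Passing inserts are collapsed to unique-sequence read counts,
    normalized to reads per million, compared across selection rounds and
    ranked into candidate reports. Also includes a synthetic SELEX read
    simulator with ground truth (binder enrichment across rounds,
    substitution sequencing error, and elongated PCR by-product chimeras)
    and a small microscale-thermophoresis dose-response module
    (baseline-subtracted delta-Fnorm transform and saturation-curve
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
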