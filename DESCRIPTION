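Package: fmlbias
Title: Functional Mutation Bias Detection of Cancer Driver Genomic Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects coding and non-coding genomic elements under positive
    selection in tumor cohorts through a local functional-mutation (FM) bias
    test. For each element the mean functional-impact score of the observed
    somatic single-nucleotide variants is compared against a Monte-Carlo
    background built by resampling mutations from all possible substitutions
    in the element, weighted by the cohort's 96-channel trinucleotide
    mutational signature. Includes construction of element catalogs (CDS,
    UTRs, intronic splice flanks, promoters, lncRNA exons) from GTF
    annotation, empirical p-values with adaptive resolution,
    Benjamini-Hochberg adjustment with per-cohort mutation thresholds,
    signature-preserving negative-control randomization, calibration and
    enrichment utilities, and a synthetic data generator for offline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
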