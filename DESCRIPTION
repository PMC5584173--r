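Package: splicekey
Title: Fusion Transcript Discovery with Paired Splice-Junction Keys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fusion transcripts in RNA-seq reads by anchoring each
    read to a table of paired 20-bp exonic key sequences flanking annotated
    introns (a splicingcode table), extending both flanks with exact identity
    against spliced transcript sequences, and filtering pseudogene,
    duplication and alternative-splicing artifacts with a self-contained
    contiguous-locus homology screen.  Includes a closed-form random-match
    error model, junction quantification normalized to splice junctions per
    million reads (NSJMR), exact 2x2 cohort association statistics, Mendelian
    consistency and genotype inference for a dominant presence/absence fusion
    marker in pedigrees, and a fully seeded synthetic-data generator (genomes,
    annotations, fusion alleles, isoforms, cohorts, error-bearing reads with
    truth sets) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
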