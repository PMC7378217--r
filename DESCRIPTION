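Package: sexbiasDE
Title: Intrinsic and Acquired Sex-Biased Gene Expression Across Life Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage analysis of sex-biased transcriptomes in endothelial
    cells: paired (twin, mother-blocked, activation-corrected) differential
    expression at birth and unpaired differential expression in adults,
    classification of genes into intrinsic versus acquired sex differences,
    hypergeometric gene-set and set-overlap tests, a Fisher exact test for
    sex-hormonal target content, promoter and gene-body conservation
    summarization from per-base score tracks, a median-based random-gene
    permutation framework, and GWAS-catalog mapped-gene enrichment. Includes a
    seeded synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
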