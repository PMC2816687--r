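Package: hzscan
Title: Hybrid-Zone Divergence Scans, Composite Linkage Disequilibrium,
    and qPCR Model Averaging
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-genetic analysis of candidate colour-pattern
    regions sampled across butterfly hybrid zones. Reads per-locus
    multiple sequence alignments of diploid population samples, extracts
    dosage-coded variant sites, and computes nucleotide diversity,
    Tajima's D with its beta-distribution significance test, Hudson's
    FST with linked-versus-unlinked Mann-Whitney contrasts, per-SNP
    chi-squared linear trend tests of genotype-by-phenotype association
    with Bonferroni control, and phase-free Burrows composite linkage
    disequilibrium with decay-by-distance summaries. Also provides
    relative-expression and Bayesian-model-averaging analysis of qPCR Ct
    tables, and a seeded synthetic-data generator (two-population
    selected-site model with haplotype-block LD, plus a neutral
    coalescent) so every stage of the pipeline can be exercised and
    calibrated without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
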