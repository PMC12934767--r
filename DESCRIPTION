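Package: allelesplice
Title: Allele-Specific Alternative Splicing Analysis from Allelic Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects allele-specific alternative splicing (ASAS) from per-SNP
    allelic read counts by comparing allelic ratios in alternatively spliced
    regions against the constitutive background of the same gene, nominates
    putative functional cis-regulatory SNPs with a genotype-imbalance
    concordance score, tests for differential allelic imbalance between
    disease groups with a beta-binomial likelihood-ratio test, and provides
    the surrounding enrichment statistics (matched-background empirical term
    enrichment, LD-aware GWAS overlap, QTL p-value enrichment, resampling
    fold changes) together with 5' UTR and proteome downstream analyses.
    A synthetic-cohort generator with genotype-dependent exon inclusion and
    overdispersed allelic counts makes the whole pipeline testable without
    access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
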