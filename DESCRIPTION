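Package: crosstraitr
Title: Cross-Trait LD Score Regression for Genetic Correlation Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates SNP heritability and pairwise genetic correlation
    from GWAS summary statistics by LD score regression, with
    summary-statistic harmonization and quality-control filters,
    sentinel-anchored genomic region exclusion, block-jackknife standard
    errors, and a multi-trait scan driver with Bonferroni control. Ships a
    synthetic-study generator (block-LD genotypes, bivariate polygenic
    effects, sample overlap, population-stratification confounding) so the
    whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
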