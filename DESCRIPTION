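Package: pathcross
Title: Cross-Disorder Pathway Convergence Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A four-layer pathway-convergence analysis for pairs of genome-wide
    association studies, working entirely from summary statistics. Implements
    harmonization of two summary-statistics dialects (PGC-style TSV and
    GWAS-VCF with ES:SE:LP fields), mean chi-squared gene-based association
    with linkage-disequilibrium correction, competitive gene-set tests over a
    priority-deduplicated panel, weighted Kolmogorov-Smirnov gene-set
    enrichment with permutation nulls and exhaustive cross-disorder
    differential enrichment, summary-based transcriptome-wide association
    from expression-prediction weights and SNP covariance with Mann-Whitney
    set enrichment, and LD score regression for partitioned heritability,
    a simplified stratified-chi-squared fallback, and cross-trait genetic
    correlation with block-jackknife standard errors. A synthetic two-trait
    generator with block LD, annotation-specific heritability multipliers,
    and a configurable genetic correlation provides ground truth for every
    layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    fgsea,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
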