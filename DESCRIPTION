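Package: aseqtl
Title: Allele-Specific Expression, Parent-of-Origin Effects and Local eQTL
    Mapping from Phased RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects allele-specific expression (ASE), parent-of-origin ASE
    (partial imprinting) and local eQTL from phased RNA-seq allele and gene
    counts. ASE and parent-of-origin effects are estimated jointly by a
    weighted regression of the log allelic ratio at transcript SNPs on the
    phased genotype of nearby driver SNPs; local eQTL are mapped with a
    pedigree-based animal model fitted by REML on TMM-normalized
    log counts-per-million. Results are combined across analyses and
    datasets by an unweighted signed-z meta-analysis, agreement between
    analyses is quantified by 2x2 chi-square tests, fold enrichment and
    direction concordance, and enrichment of trait QTL among eQTL is tested
    with a circular-shift permutation null and a gene-adjusted linear model.
    A synthetic-data generator (pedigree gene-drop, binomial allelic counts,
    pedigree-correlated gene counts, GWAS indicator vectors) makes the full
    pipeline testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
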