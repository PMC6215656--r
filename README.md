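# aseqtl

Detects cis-regulatory variation and partial imprinting from phased
RNA-seq data, for quantitative geneticists working with pedigreed
populations (livestock above all) where genotypes can be phased so that
the maternal and paternal haplotype of every individual is known.

A cis eQTL shows up twice: as allelic imbalance at transcript SNPs within
heterozygotes (allele-specific expression, ASE) and as an association
between nearby genotypes and total expression (a local eQTL). Allelic
imbalance can also come from imprinting — expression driven by the
transmitting parent rather than the allele. `aseqtl` separates these
signals, combines them, and tests whether trait QTL are enriched for
eQTL.

## The models

**Joint PO-ASE / ASE regression.** For a transcript SNP (tSNP) paired
with each driver SNP (dSNP) within 50 kb, heterozygous animals contribute
rows to a weighted regression

y\_i = α + x₁ᵢ b₁ + eᵢ,  e ~ N(0, T⁻¹ I σ²ₑ)

with y = log₁₀(maternal / paternal count), weight T = total allele count,
and x₁ ∈ {−1, 0, +1} the phased dSNP coding (−1: reference allele from
the sire; +1: from the dam; 0: homozygous). The intercept α captures a
parent-of-origin effect (partial imprinting); the slope b₁ captures
cis-driven ASE. Records need both alleles observed and coverage > 10;
tSNPs need heterozygotes with opposite sire transmissions.

**Local eQTL animal model.** On TMM-normalized log₁₀ cpm,

y = 1α + X₂b₂ + Zu + e,  u ~ N(0, A σ²ᵤ)

with A the pedigree numerator relationship matrix, fitted by REML
(eigendecomposition + 1-D profile of σ²ᵤ/σ²ₑ).

**Combination and overlap.** Signed-z meta-analysis
z̄\* = √((Σzᵢ)²/n); FDR estimation FDR = P(1 − A/T)/((A/T)(1 − P));
2×2 chi-square / fold enrichment / direction concordance between
analyses; and QTL–eQTL enrichment against a circular-shift permutation
null with empirical rank thresholds, plus per-gene tests and a
gene-adjusted linear model.

A synthetic-data generator (pedigree gene-drop, binomial allelic counts,
pedigree-correlated gene counts, GWAS indicator vectors) exercises the
whole pipeline without external data.

## Worked example

```r
library(aseqtl)

bundle <- simulate_dataset(sim_config(seed = 7L))   # 100 animals, 10 genes
res <- ase_scan(bundle$allele_counts, bundle$genotypes)
merge(res, bundle$truth, by = c("tsnp_id", "dsnp_id"))[1:3, 1:9]
#>   tsnp_id dsnp_id  n alpha se_alpha  p_alpha    b1  se_b1     p_b1
#> 1  g01_t1  g01_d1 48 0.246   0.0142 9.05e-22 0.358 0.0217 6.80e-21
#> 2  g01_t2  g01_d1 42 0.188   0.0134 4.74e-17 0.320 0.0179 1.10e-20
#> 3  g02_t1  g02_d1 35 0.218   0.0148 4.43e-16 0.313 0.0239 1.22e-14
```

The generative truth is α = 0.2 and b₁ = 0.3: each causal dSNP–tSNP pair
recovers both a parent-of-origin intercept and a cis slope near truth,
with p-values reflecting ~40 informative heterozygotes at depth ~100.

```r
expr <- normalize_expression(bundle$gene_counts)
eqtl <- eqtl_scan(expr, bundle$genotypes, bundle$annotation,
                  ped = bundle$pedigree)
subset(eqtl, dsnp_id == "g01_d1")[1, c(1:5, 7:8)]
#>   gene_id dsnp_id    b2  se_b2    p_b2 sigma2_u_hat sigma2_e_hat
#> 3  gene01  g01_d1 0.278 0.0495 1.9e-08       0.0715       0.0198
```

b₂ (truth 0.25) is the alternate-allele dose effect on log₁₀ expression
under the pedigree mixed model. FDR from significance counts, e.g. 11,717
significant of 3,749,255 tests at p < 10⁻⁴:

```r
compute_fdr(1e-4, 11717, 3749255)
#> [1] 0.03190161      # i.e. 3%
overlap_from_counts(4152056, 18943, 10989, 1375)$fold_enrichment
#> [1] 27.43           # observed joint hits vs. chance expectation
```

`run_pipeline(sim_config(seed = 7L), "out/")` chains every stage
(simulate → ASE → eQTL → meta → comparison → QTL overlap) and writes one
TSV per stage plus a JSON manifest; reruns with the same config are
byte-identical.

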