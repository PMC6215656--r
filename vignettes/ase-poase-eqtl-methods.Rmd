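---
title: "Separating cis-regulatory and parent-of-origin signals in phased RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating cis-regulatory and parent-of-origin signals in phased RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseqtl)
```

## The problem

A variant that alters the expression of the gene copy on its own
chromosome (a cis eQTL) is visible twice in RNA-seq data from heterozygous
individuals: as allelic imbalance at SNPs inside the transcript (ASE), and
as an association between nearby genotypes and total expression across
individuals (a local eQTL). Allelic imbalance can, however, also arise
from genomic imprinting, where expression depends on which parent
transmitted the allele rather than on the allele itself. With genotypes
phased through a pedigree so that the maternal and paternal haplotype of
every animal is known, the two causes are separable within one model, and
that separation is the core of this package.

## The joint PO-ASE / ASE model

For one transcript SNP (tSNP) and one candidate driver SNP (dSNP) within
50 kb, each informative heterozygote contributes one row:

$$y_i = \alpha + x_{1i}\, b_1 + e_i,
  \qquad e \sim N(0,\, T^{-1} I \sigma^2_e)$$

where $y_i = \log_{10}(\text{maternal count}/\text{paternal count})$ at
the tSNP, $T_i$ is the total allele count used as the regression weight
(the log-ratio's sampling variance is proportional to $1/T$), and $x_{1i}$
codes the phased dSNP genotype: homozygotes 0, heterozygotes $-1$ when the
reference allele came from the sire and $+1$ when it came from the dam
(`code_dsnp()`). A pure parent-of-origin effect shifts all three genotype
classes equally and loads on the intercept $\alpha$; a cis-acting driver
allele reverses the imbalance between the $-1$ and $+1$ classes and loads
on the slope $b_1$. Both are estimated jointly by weighted least squares
(`fit_ase_model()`), with two-sided t-tests on $n-2$ degrees of freedom.

Eligibility rules, applied before fitting (`filter_informative_tsnps()`,
`tsnp_is_analyzable()`):

* the animal is heterozygous at the tSNP in the genotype data;
* both alleles were observed at least once — strict monoallelic
  expression is excluded because it cannot be distinguished from a
  genotyping or reference error (a consequence is that complete imprinting
  is out of reach by design; the intercept detects *partial* imprinting);
* total coverage strictly exceeds 10 on the averaged counts;
* the tSNP has heterozygotes that received *opposite* alleles from their
  sires — otherwise $\alpha$ and $b_1$ are confounded.

Counts come from aligning each animal's reads to both its maternal and its
paternal customized reference; the two counts per allele are combined by
their arithmetic mean unconditionally (averaging equal counts is the
identity, so no branch is needed). Averaged counts may be non-integer and
are used as-is in $y$ and $T$. The coverage filter is applied to the
averaged total; we fit only pairs with at least 3 informative rows so the
residual variance has at least one degree of freedom, and pairs with a
constant $x_1$ keep the intercept (df $n-1$) with the slope flagged
inestimable.

The false discovery rate at threshold $P$ with $A$ of $T$ tests
significant is estimated as
$FDR = P(1 - A/T) \,/\, \big((A/T)(1 - P)\big)$ (`compute_fdr()`); it
equals 1 exactly when significance occurs at the chance rate $A = PT$.

## Local eQTL mapping

Gene counts are filtered to genes expressed (count $> 0$) in strictly more
than 25% of animals, TMM-normalized (via edgeR), converted to counts per
million of the TMM-adjusted library size, and taken to
$y = \log_{10}(\mathrm{cpm} + 1)$ (`normalize_expression()`). The +1
offset is our choice for zero handling: genes passing the 25% filter can
still contain zeros, and the offset keeps them finite while leaving
moderately-to-highly expressed genes essentially on the raw log scale.

Each SNP within 50 kb of the gene's annotated span (start $-$ 50 kb to
end $+$ 50 kb, inclusive) is tested with the animal model

$$y = 1\alpha + X_2 b_2 + Zu + e, \qquad
  u \sim N(0, A\sigma^2_u),\; e \sim N(0, I\sigma^2_e)$$

where $x_2 \in \{0,1,2\}$ counts alternate-allele copies and $A$ is the
pedigree numerator relationship matrix built by the tabular method
(`numerator_relationship_matrix()`). The fit (`fit_eqtl()`) profiles the
restricted likelihood over the variance ratio
$\lambda = \sigma^2_u/\sigma^2_e$ using one eigendecomposition of $A$ per
animal set, so each gene–SNP pair reduces to a deterministic
one-dimensional optimization (tolerance $10^{-8}$ on $\log\lambda$, with
an explicit comparison against the $\lambda = 0$ boundary); $(\alpha,
b_2)$ are then generalized-least-squares estimates at the REML variances.
The default test on $b_2$ is a Wald z; a t reference with $n-2$ df is
available via `test = "t"`. With $\sigma^2_u$ at the boundary the fit
reduces exactly to ordinary least squares, which the tests verify.

### Sign conventions

$b_1 > 0$ means the reference allele increases expression (maternal
reference raises the maternal/paternal ratio); $b_2 > 0$ means the
*alternate* allele increases expression. Both scans therefore also report
`effect_ref` ($b_1$ and $-b_2$ respectively), a single orientation in
which positive always means "reference allele increases expression".
Meta-analysis and concordance computations use `effect_ref`.

## Combining and comparing analyses

**Signed-z meta-analysis** (`signed_z()`, `combine_z()`,
`meta_analyze()`). Each estimate $U_i$ with standard error $s_i$ becomes
$t_i = U_i/s_i$, its two-sided p-value $p_i$ with the analysis's degrees
of freedom, and $z_i = \mathrm{sign}(U_i)\,|\Phi^{-1}(p_i/2)|$. The
mapping from a two-sided $p$ back to a normal quantile is sign-ambiguous
on its own; attaching the sign of $U_i$ makes the $z_i$ standard normal
under the null while preserving direction, which is the interpretation we
adopt. Matched estimates combine as
$\bar z^* = \sqrt{(\sum_i z_i)^2 / n}$, unweighted, compared two-sided
against N(0,1); the signed sum is reported alongside the non-negative
$\bar z^*$ so direction remains recoverable. Keys present in a single
table pass through with $n = 1$. The pooled alternative
(`pool_analyses()`) concatenates rows untouched with a provenance column
and never recombines evidence.

**Agreement statistics** (`crosstab()`). Two result tables restricted to
their common keys are classified significant/not at a threshold (default
$10^{-3}$); the 2×2 table gets a Pearson chi-square (1 df, no continuity
correction by default — expected counts in these comparisons are large;
Yates is behind a flag), fold enrichment
$n_\text{both} / (n_A n_B / n)$, and direction concordance — the fraction
of both-significant keys whose oriented effects share a sign, zero
effects excluded. When a key maps to several rows (a dSNP paired with
several tSNPs in a gene), each analysis is collapsed to the row with the
smallest p-value per key before classification.

## QTL–eQTL overlap

Genome-wide, significance indicators for a trait (QTL) and for expression
(eQTL) are cross-tabulated and the Pearson chi-square is signed: positive
when the observed both-significant count exceeds its independence
expectation, negative otherwise (`signed_overlap_chi2()`). Because linkage
disequilibrium clumps significant SNPs, the theoretical $\chi^2_1$
reference is invalid; the null is built by circularly rotating the
genome-ordered GWAS vector by a random offset drawn uniformly between 10%
and 90% of the number of SNPs (`permutation_null()`). Rotating the whole
concatenated vector as one object preserves the local correlation
structure of both vectors and the margins of every permuted table exactly
(an invariant the tests check). Offsets are drawn with replacement — the
draw scheme is not dictated by the rotation idea itself, so a fixed-grid
option exists. Empirical thresholds are order statistics of the sorted
signed values at ranks $\lceil 0.95\,n_\text{perm}\rceil$ and
$\lfloor 0.05\,n_\text{perm}\rfloor$ (9500 and 500 at the default
10,000), and enrichment is declared only on strict exceedance of the
upper threshold, one-tailed, since only enrichment is of interest;
impoverishment is reported descriptively.

Two finer-grained views complement the global test: per-gene 2×2
chi-squares restricted to genes whose 50-kb window contains at least one
QTL and one eQTL (`per_gene_overlap()`), and the gene-adjusted linear
model $y = 1\alpha + X_3 b_3 + X_4 b_4 + e$ regressing the eQTL indicator
on gene membership plus the QTL indicator (`fit_gene_adjusted_model()`),
where a positive $b_4$ means trait-associated SNPs are enriched for
expression associations *within* genes. One gene level is absorbed into
the intercept; both one-sided ($b_4 > 0$) and two-sided p-values are
reported because the enrichment hypothesis is directional. The design
needs a partition of SNPs into genes, so SNPs falling in two windows are
assigned to the nearest gene, ties to the lexicographically smaller id
(`assign_snps_to_genes()`).

## The synthetic-data generator

`simulate_dataset()` produces every input under one seed: a pedigree
(founders plus random-pairing generations), a genome layout, gene-drop
phased genotypes, allelic counts, gene counts, and a GWAS table, plus a
truth table. Defaults define the study conditions and are not tuning
knobs:

| parameter | default | meaning |
|---|---|---|
| founders / generations / family | 40 / 1 / 3 | 100 animals with full-sib structure |
| genes, spacing | 10, 200 kb | windows never overlap, so gene assignment is unique |
| tSNPs, dSNPs per gene | 2, 3 | drivers placed 5–45 kb upstream |
| founder MAF | 0.3 | common variants, most tSNPs informative |
| depth mean, dispersion | 100, 5 | negative-binomial site coverage, truncated at $T \ge 11$ |
| $\alpha$, $b_1$ | 0.2, 0.3 | log10-ratio scale, clearly detectable at depth 100 |
| $b_2$ | 0.25 | log10-expression scale |
| $\sigma^2_u$, $\sigma^2_e$ | 0.05, 0.05 | heritability 0.5 of residual log expression |
| overlap probability | 0.5 | over a 1% background GWAS significance rate |

Design choices worth stating:

* **Linkage blocks, not recombination.** Transmission is per gene window:
  a parent passes one whole haplotype of the block. At 50 kb,
  recombination is negligible and modeling it would add nothing testable.
* **Binomial allelic counts.** The maternal count is
  $\mathrm{Bin}(T, p)$ with $p = r/(1+r)$, $r = 10^{\alpha + b_1 x_1}$.
  The analysis model itself only asserts that the log-ratio's error
  variance is $\propto 1/T$; the binomial is our generative choice
  consistent with that weighting, not the only one.
* **Truncation.** Depths are redrawn until $T \ge 11$ so simulated
  records pass the coverage filter by construction; `truncate = FALSE`
  emits raw depths so the filter itself can be tested. Records landing on
  a zero count for either allele are likewise redrawn, mirroring the
  eligibility rules.
* **Gene counts.** Latent log10 expression is
  $\mu + b_2 x_2 + u + e$ with $u \sim MVN(0, A\sigma^2_u)$ drawn through
  the Cholesky factor of $A$; observed counts are Poisson at
  $10^{\text{latent}}$ times a per-animal library scaling.
* **GWAS.** Significance indicators are Bernoulli — `overlap_prob` for
  true eQTL SNPs, a background rate otherwise — with p-values, effects and
  SEs drawn consistently with the indicators.

What the generator does *not* emulate: mapping bias between the parental
references (counts arrive pre-averaged), sequencing or imputation errors
in phasing, LD decay beyond the gene window, multi-tissue structure, and
trans-acting variation. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated generative assumptions, not
robustness to those artifacts.

## Numerical behavior and known limitations

* **Finite-depth bias of the log ratio.** Under binomial sampling,
  $E[\log(m/(T-m))] \ne \log(p/q)$ at finite $T$; the weighted fit
  inherits a transformation bias of order $(p/q - q/p)/(2T\ln 10)$ per
  record — roughly $+0.002$ on $\hat\alpha$ at depth 100 and effect sizes
  around 0.2–0.3, vanishing as depth grows (the test suite checks
  recovery at depth 1000). Replication-scale averages of the estimates
  can resolve this bias; single-pair inference cannot, and interval
  coverage stays near nominal.
* **Slight anticonservativeness of the intercept test.** The binomial
  log-ratio has slightly heavier tails than the normal working model at
  moderate depth; the intercept's type-I error at nominal 0.05 sits near
  0.053 at depth 100.
* **Discreteness of the permutation test at sparse margins.** With very
  few significant SNPs the signed chi-square takes few distinct values,
  ties accumulate at the empirical threshold, and the strict-exceedance
  rule becomes conservative. The calibration test uses 5% marginal
  significance rates (N = 5000, expected joint count 12.5), the regime
  where genome-wide analyses with thousands of significant SNPs operate
  and the statistic is effectively continuous.
* **REML at the boundary.** $\hat\sigma^2_u = 0$ is returned honestly
  when the profile likelihood prefers the boundary; with $A = I$ the
  split between $u$ and $e$ is unidentified and only their sum is
  meaningful.
* **FDR estimator.** Undefined at $A = 0$ (returned as `NA` with a
  warning) and may exceed 1 when significance falls below the chance
  rate; it is reported as computed, not clipped.

## Problem sizes used in the tests

The suite exercises the estimators at desk scale: 500 replicates of a
40-animal pair at depth 100 for recovery and interval coverage, 2,000
null pairs for size, 200 replicates of a 100-animal pedigree for the
animal model, and 200 outer replicates of a 5,000-SNP genome with 1,000
rotations each for permutation calibration. These sizes keep the full
suite under a minute while leaving Monte-Carlo error well below the
effect sizes being checked.

## A minimal run

```{r, eval = FALSE}
cfg <- sim_config(seed = 7L)
manifest <- run_pipeline(cfg, "pipeline_out", n_perm = 2000)
```

This writes the simulated inputs, one TSV per analysis stage, and a JSON
manifest with the seed, version and row counts; rerunning with the same
configuration reproduces every file byte-for-byte.
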