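# Pearson 2x2 chi-square from margins and the joint count; used in the
# permutation loop where circular shifts leave the margins fixed.
.chi2_from_margins <- function(n, a, b, o) {
  n <- as.numeric(n); a <- as.numeric(a); b <- as.numeric(b)
  o <- as.numeric(o)
  num <- n * (o * n - a * b)^2
  den <- a * b * (n - a) * (n - b)
  ifelse(den == 0, NA_real_, num / den)
}

#' Signed chi-square overlap statistic between two significance vectors
#'
#' Pearson chi-square (1 df) of the 2x2 cross-tabulation of two aligned
#' 0/1 significance indicators, signed positive when the observed
#' both-significant count exceeds its independence expectation
#' (enrichment) and negative when below it (impoverishment).
#'
#' @param qtl_sig,eqtl_sig Logical/0-1 vectors in shared genome order.
#' @return Signed statistic; `NA` with a warning when either vector is
#'   degenerate (all 0 or all 1).
#' @export
signed_overlap_chi2 <- function(qtl_sig, eqtl_sig) {
  x <- as.logical(qtl_sig); y <- as.logical(eqtl_sig)
  stopifnot(length(x) == length(y))
  n <- length(x); a <- sum(x); b <- sum(y); o <- sum(x & y)
  if (a %in% c(0L, n) || b %in% c(0L, n)) {
    warning("degenerate significance vector; overlap chi-square undefined")
    return(NA_real_)
  }
  stat <- .chi2_from_margins(n, a, b, o)
  sign_ <- sign(o - a * b / n)
  if (sign_ == 0) 0 else sign_ * stat
}

#' Circular-shift permutation null for the signed overlap statistic
#'
#' Builds the null distribution of the signed chi-square by rotating the
#' genome-ordered GWAS significance vector by a random offset between 10%
#' and 90% of the number of SNPs (the whole concatenated vector is rotated
#' as one object, preserving the local correlation structure of both
#' vectors and the margins of every permuted 2x2 table exactly) and
#' recomputing the statistic against the unshifted eQTL vector. Empirical
#' thresholds are the order statistics of the sorted signed values at ranks
#' `ceiling(0.95 n_perm)` (enrichment) and `floor(0.05 n_perm)`
#' (impoverishment) — ranks 9500 and 500 at the default 10,000 replicates.
#'
#' @param qtl_sig,eqtl_sig Aligned significance indicators (length >= 10).
#' @param n_perm Number of rotations (default 10000).
#' @param shift_range Offset range as fractions of the vector length
#'   (default `c(0.10, 0.90)`).
#' @param seed Optional integer seed for the offset draws.
#' @param scheme `"random"` draws offsets uniformly with replacement;
#'   `"grid"` uses `n_perm` evenly spaced offsets across the range.
#' @return List of class `signed_chi2_null`: `stats` (signed values),
#'   `upper`, `lower`, `n_perm`, `shifts`.
#' @export
permutation_null <- function(qtl_sig, eqtl_sig, n_perm = 10000,
                             shift_range = c(0.10, 0.90), seed = NULL,
                             scheme = c("random", "grid")) {
  scheme <- match.arg(scheme)
  x <- as.logical(qtl_sig); y <- as.logical(eqtl_sig)
  n <- length(x)
  stopifnot(length(y) == n, n >= 10)
  lo <- ceiling(shift_range[1] * n)
  hi <- floor(shift_range[2] * n)
  if (hi < lo) stop("empty shift range")
  if (!is.null(seed)) set.seed(seed)
  shifts <- if (scheme == "random") {
    sample(lo:hi, n_perm, replace = TRUE)
  } else {
    unique(round(seq(lo, hi, length.out = n_perm)))
  }
  a <- sum(x); b <- sum(y)
  yi <- which(y)
  stats <- vapply(shifts, function(s) {
    # x rotated by s: element i of the rotated vector is x[(i - s - 1) mod n + 1]
    o <- sum(x[(yi - s - 1L) %% n + 1L])
    st <- .chi2_from_margins(n, a, b, o)
    sgn <- sign(o - a * b / n)
    if (is.na(st)) NA_real_ else if (sgn == 0) 0 else sgn * st
  }, numeric(1))
  sorted <- sort(stats)
  structure(list(stats = stats,
                 upper = sorted[ceiling(0.95 * length(stats))],
                 lower = sorted[max(floor(0.05 * length(stats)), 1L)],
                 n_perm = length(stats), shifts = shifts),
            class = "signed_chi2_null")
}

#' Declare enrichment against a permutation null
#'
#' One-tailed test against the empirical enrichment threshold (only
#' enrichment is of biological interest): significant enrichment iff the
#' observed signed statistic strictly exceeds the upper threshold.
#' Impoverishment below the lower threshold is reported descriptively.
#'
#' @param observed Observed signed statistic from [signed_overlap_chi2()].
#' @param null A `signed_chi2_null`.
#' @return `"significant_enrichment"`, `"significant_impoverishment"` or
#'   `"neither"`.
#' @export
enrichment_test <- function(observed, null) {
  stopifnot(inherits(null, "signed_chi2_null"))
  if (is.na(observed)) return("neither")
  if (observed > null$upper) "significant_enrichment"
  else if (observed < null$lower) "significant_impoverishment"
  else "neither"
}

#' Per-gene QTL/eQTL overlap tests
#'
#' For each gene, SNPs within the window are cross-tabulated as
#' significant-or-not for the trait and for expression and tested by a
#' 2x2 chi-square. Only genes whose window contains at least one QTL and
#' at least one eQTL are tested; the rest are skipped.
#'
#' @param snp_positions Data.frame `snp_id`, `chrom`, `pos` in genome order.
#' @param qtl_sig,eqtl_sig Indicators aligned with `snp_positions`.
#' @param annotation Gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param window_bp Gene window (default 50000).
#' @return Data.frame: `gene_id`, `n_snps`, `n_qtl`, `n_eqtl`, `n_both`,
#'   `chi2`, `p_chi2`.
#' @export
per_gene_overlap <- function(snp_positions, qtl_sig, eqtl_sig, annotation,
                             window_bp = 50000) {
  qtl_sig <- as.logical(qtl_sig); eqtl_sig <- as.logical(eqtl_sig)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    in_win <- snp_positions$chrom == g$chrom &
      snp_positions$pos >= g$start - window_bp &
      snp_positions$pos <= g$end + window_bp
    if (!any(qtl_sig[in_win]) || !any(eqtl_sig[in_win])) return(NULL)
    n <- sum(in_win); a <- sum(qtl_sig[in_win]); b <- sum(eqtl_sig[in_win])
    o <- sum(qtl_sig[in_win] & eqtl_sig[in_win])
    st <- .chi2_from_margins(n, a, b, o)
    data.frame(gene_id = g$gene_id, n_snps = n, n_qtl = a, n_eqtl = b,
               n_both = o, chi2 = st,
               p_chi2 = stats::pchisq(st, 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_snps = integer(0),
                      n_qtl = integer(0), n_eqtl = integer(0),
                      n_both = integer(0), chi2 = numeric(0),
                      p_chi2 = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Gene-adjusted linear model for genome-wide QTL/eQTL association
#'
#' Ordinary least squares of the eQTL significance indicator on an
#' intercept, gene-membership indicators (one level absorbed into the
#' intercept) and the QTL indicator:
#' \deqn{y = 1\alpha + X_3 b_3 + X_4 b_4 + e}
#' so that \eqn{b_4} measures, within genes, whether trait-associated SNPs
#' are more often expression-associated. A significantly positive
#' \eqn{b_4} indicates QTL are enriched for eQTL; both the one-sided
#' (b4 > 0) and two-sided p-values are reported.
#'
#' @param eqtl_sig 0/1 response per SNP.
#' @param gene Gene assignment per SNP (each SNP in exactly one gene; SNPs
#'   within two windows should be pre-assigned to the nearest gene).
#' @param qtl_sig 0/1 QTL indicator per SNP.
#' @return List of class `gene_adjusted_fit`: `b4`, `se_b4`, `p_two_sided`,
#'   `p_one_sided`, `alpha`, `b3` (named per-gene effects relative to the
#'   absorbed level), `n_snps`, `df`; errors flagged via `b4 = NA` when the
#'   QTL indicator is constant.
#' @export
fit_gene_adjusted_model <- function(eqtl_sig, gene, qtl_sig) {
  y <- as.numeric(eqtl_sig)
  x4 <- as.numeric(qtl_sig)
  gene <- factor(gene)
  n <- length(y)
  stopifnot(length(gene) == n, length(x4) == n)
  if (length(unique(x4)) < 2) {
    warning("QTL indicator constant; b4 inestimable")
    return(structure(list(b4 = NA_real_, se_b4 = NA_real_,
                          p_two_sided = NA_real_, p_one_sided = NA_real_,
                          alpha = NA_real_, b3 = NULL, n_snps = n, df = NA),
                     class = "gene_adjusted_fit"))
  }
  fit <- if (nlevels(gene) > 1) stats::lm(y ~ gene + x4)
    else stats::lm(y ~ x4)
  cf <- summary(fit)$coefficients
  df <- fit$df.residual
  t4 <- cf["x4", 3]
  b3 <- stats::coef(fit)[grep("^gene", names(stats::coef(fit)))]
  structure(list(b4 = cf["x4", 1], se_b4 = cf["x4", 2],
                 p_two_sided = 2 * stats::pt(abs(t4), df, lower.tail = FALSE),
                 p_one_sided = stats::pt(t4, df, lower.tail = FALSE),
                 alpha = cf["(Intercept)", 1], b3 = b3,
                 n_snps = n, df = df),
            class = "gene_adjusted_fit")
}

#' Assign SNPs to their nearest gene
#'
#' Partition needed by the gene-adjusted design: each SNP within
#' `window_bp` of at least one gene is assigned to the nearest gene
#' (distance 0 inside the span; ties broken toward the lexicographically
#' smaller gene id); SNPs in no window get `NA`.
#'
#' @param snp_positions Data.frame `snp_id`, `chrom`, `pos`.
#' @param annotation Gene annotation.
#' @param window_bp Window (default 50000).
#' @return Character vector of gene ids aligned with `snp_positions`.
#' @export
assign_snps_to_genes <- function(snp_positions, annotation,
                                 window_bp = 50000) {
  ann <- annotation[order(annotation$gene_id), , drop = FALSE]
  vapply(seq_len(nrow(snp_positions)), function(i) {
    p <- snp_positions$pos[i]
    cand <- ann[ann$chrom == snp_positions$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    d <- pmax(cand$start - p, p - cand$end, 0)
    d[d > window_bp] <- NA
    if (all(is.na(d))) return(NA_character_)
    cand$gene_id[which.min(d)]
  }, character(1))
}
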