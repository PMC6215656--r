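#' Pearson chi-square test of a 2x2 table
#'
#' Plain Pearson statistic \eqn{\sum (O-E)^2/E} with 1 df and, by default,
#' no continuity correction (expected counts in cross-analysis comparisons
#' are large); a Yates-corrected variant is available behind the flag.
#'
#' @param tab 2x2 matrix of counts.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List `statistic`, `p_value`, `expected`; statistic is `NA` with
#'   a warning when any expected cell is zero.
#' @export
chi2_2x2 <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E == 0)) {
    warning("zero expected cell; chi-square undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, expected = E))
  }
  dev <- abs(tab - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = E)
}

#' Overlap statistics from pre-tabulated significance counts
#'
#' Builds the 2x2 significant/non-significant table from its marginal and
#' joint counts and returns the chi-square test, the fold enrichment
#' (observed both-significant count over the count expected were the two
#' classifications independent), and optionally the direction concordance.
#'
#' @param n_total Number of tests in common.
#' @param n_sig_a,n_sig_b Significant counts in each analysis.
#' @param n_sig_both Count significant in both.
#' @param concordance Optional concordance fraction to carry through.
#' @param correct Yates correction flag passed to [chi2_2x2()].
#' @return One-row data.frame of class `overlap_table`: counts, `chi2`,
#'   `p_chi2`, `fold_enrichment`, `concordance`.
#' @export
overlap_from_counts <- function(n_total, n_sig_a, n_sig_b, n_sig_both,
                                concordance = NA_real_, correct = FALSE) {
  stopifnot(n_sig_both <= min(n_sig_a, n_sig_b),
            n_sig_a <= n_total, n_sig_b <= n_total)
  tab <- matrix(c(n_sig_both, n_sig_a - n_sig_both,
                  n_sig_b - n_sig_both,
                  n_total - n_sig_a - n_sig_b + n_sig_both),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("sig", "ns"), B = c("sig", "ns")))
  ct <- chi2_2x2(tab, correct = correct)
  expected_both <- n_sig_a * n_sig_b / n_total
  out <- data.frame(n_total = n_total, n_sig_a = n_sig_a, n_sig_b = n_sig_b,
                    n_sig_both = n_sig_both, chi2 = ct$statistic,
                    p_chi2 = ct$p_value,
                    fold_enrichment = n_sig_both / expected_both,
                    concordance = concordance)
  class(out) <- c("overlap_table", "data.frame")
  out
}

# Collapse a result table to one row per key. For "any tSNP in the gene"
# matching the row with the smallest p per key is kept.
.collapse_results <- function(res, by, p_col, effect_col) {
  key <- do.call(paste, c(res[by], sep = "\r"))
  best <- tapply(seq_len(nrow(res)), key, function(i) i[which.min(res[[p_col]][i])])
  out <- res[unlist(best), c(by, p_col, effect_col), drop = FALSE]
  names(out) <- c(by, "p", "effect")
  out$key <- do.call(paste, c(out[by], sep = "\r"))
  out
}

#' Cross-tabulate significance between two result tables
#'
#' Restricts both analyses to the keys tested in both, classifies each key
#' as significant or not at `p_threshold`, and computes the 2x2 chi-square,
#' fold enrichment and direction concordance. When a key (e.g. dSNP + gene)
#' maps to several rows (several tSNPs), each analysis is collapsed to the
#' row with the smallest p-value per key before classification. Effects in
#' `effect_col` must share a reference-allele orientation across the two
#' tables (use the scans' `effect_ref`).
#'
#' @param res_a,res_b Result data.frames.
#' @param by Key columns shared by both tables.
#' @param p_threshold Significance threshold (default 1e-3).
#' @param p_col,effect_col Column names for p-values and oriented effects.
#' @param correct Yates correction flag.
#' @return One-row `overlap_table` (see [overlap_from_counts()]);
#'   concordance is the fraction of both-significant keys with equal
#'   effect signs (zero effects excluded; `NA` when no key is significant
#'   in both).
#' @export
crosstab <- function(res_a, res_b, by, p_threshold = 1e-3,
                     p_col = "p", effect_col = "effect", correct = FALSE) {
  a <- .collapse_results(res_a, by, p_col, effect_col)
  b <- .collapse_results(res_b, by, p_col, effect_col)
  common <- intersect(a$key, b$key)
  if (length(common) == 0) stop("no keys tested in both analyses")
  a <- a[match(common, a$key), ]
  b <- b[match(common, b$key), ]
  sig_a <- a$p < p_threshold
  sig_b <- b$p < p_threshold
  both <- sig_a & sig_b
  conc <- as.numeric(direction_concordance(a$effect[both], b$effect[both]))
  overlap_from_counts(length(common), sum(sig_a), sum(sig_b), sum(both),
                      concordance = conc, correct = correct)
}

#' Direction concordance between paired effect estimates
#'
#' Fraction of pairs in which the same allele increases expression, i.e.
#' the two oriented effects share a sign. Pairs where either effect is
#' exactly zero carry no direction and are excluded (their number is
#' reported in the `n_zero` attribute).
#'
#' @param effect_a,effect_b Oriented effect vectors of equal length
#'   (typically restricted to both-significant keys).
#' @return Fraction in \[0, 1\], or `NA` when no nonzero pair exists.
#' @export
direction_concordance <- function(effect_a, effect_b) {
  stopifnot(length(effect_a) == length(effect_b))
  nz <- effect_a != 0 & effect_b != 0
  out <- if (!any(nz)) NA_real_
    else mean(sign(effect_a[nz]) == sign(effect_b[nz]))
  attr(out, "n_zero") <- sum(!nz)
  out
}
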