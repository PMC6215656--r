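#' Code a phased driver-SNP genotype as -1 / 0 / +1
#'
#' Homozygotes are coded 0; a heterozygote that inherited the reference
#' allele from its sire is coded -1 and one that inherited it from its dam
#' is coded +1. This is the regressor of the joint PO-ASE/ASE model: under a
#' pure parent-of-origin effect the three genotype classes share the same
#' allelic imbalance (only the intercept moves), while a cis-acting driver
#' allele reverses the imbalance between the -1 and +1 classes (slope).
#'
#' @param paternal_allele,maternal_allele Vectors in \{0, 1\}
#'   (0 = reference).
#' @return Integer vector in \{-1, 0, +1\}.
#' @export
code_dsnp <- function(paternal_allele, maternal_allele) {
  stopifnot(all(paternal_allele %in% c(0, 1)),
            all(maternal_allele %in% c(0, 1)))
  ifelse(paternal_allele == maternal_allele, 0L,
         ifelse(paternal_allele == 0L, -1L, 1L))
}

#' Filter allele-count records to informative heterozygous observations
#'
#' Joins count records to phased genotypes and keeps a record only when the
#' animal is heterozygous at the tSNP in the genotype data, both alleles
#' were seen at least once (excluding strict monoallelic expression, which
#' cannot be distinguished from a genotyping error), and total coverage
#' exceeds `min_coverage` on the averaged counts. Counts with no matching
#' genotype are dropped and counted.
#'
#' @param counts `allele_counts` table.
#' @param genotypes `phased_genotypes` table (tSNP genotypes).
#' @param min_coverage Coverage filter; records kept need
#'   `total > min_coverage` (default 10).
#' @return Filtered `allele_counts` with added phase columns
#'   `paternal_allele`, `maternal_allele` and attribute `n_dropped`
#'   (named breakdown).
#' @export
filter_informative_tsnps <- function(counts, genotypes, min_coverage = 10) {
  key_c <- paste(counts$animal_id, counts$tsnp_id)
  key_g <- paste(genotypes$animal_id, genotypes$snp_id)
  idx <- match(key_c, key_g)
  unmatched <- is.na(idx)
  pat <- genotypes$paternal_allele[idx]
  mat <- genotypes$maternal_allele[idx]
  het <- !unmatched & pat != mat
  covered <- counts$maternal_count >= 1 & counts$paternal_count >= 1 &
    counts$total > min_coverage
  keep <- het & covered
  dropped <- c(no_genotype = sum(unmatched),
               homozygous = sum(!unmatched & !het),
               low_coverage = sum(het & !covered))
  out <- counts[keep, , drop = FALSE]
  out$paternal_allele <- pat[keep]
  out$maternal_allele <- mat[keep]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' Is a tSNP analyzable for parent-of-origin effects?
#'
#' A tSNP can separate a parent-of-origin effect from cis-driven ASE only
#' when its informative heterozygotes received opposite alleles from their
#' sires: at least one animal got the reference allele from the sire and at
#' least one from the dam.
#'
#' @param filtered `allele_counts` restricted to one tSNP, as returned by
#'   [filter_informative_tsnps()] (needs the phase columns).
#' @return Logical scalar.
#' @export
tsnp_is_analyzable <- function(filtered) {
  if (nrow(filtered) == 0) return(FALSE)
  any(filtered$paternal_allele == 0) && any(filtered$maternal_allele == 0)
}

#' Enumerate dSNP-tSNP pairs within a window
#'
#' Every SNP on the same chromosome within `window_bp` of the tSNP position
#' (inclusive at the boundary) is paired with it as a candidate driver,
#' including the tSNP itself (distance 0).
#'
#' @param tsnp_ids Character vector of analyzable tSNP ids.
#' @param snp_positions Data.frame with `snp_id`, `chrom`, `pos` for all
#'   candidate driver SNPs (typically every genotyped SNP).
#' @param window_bp Window half-width in bp (default 50000).
#' @return Data.frame with columns `tsnp_id`, `dsnp_id`, `distance`.
#' @export
enumerate_pairs <- function(tsnp_ids, snp_positions, window_bp = 50000) {
  tpos <- snp_positions[match(tsnp_ids, snp_positions$snp_id), , drop = FALSE]
  if (anyNA(tpos$pos)) stop("tSNP missing from snp_positions")
  out <- lapply(seq_along(tsnp_ids), function(i) {
    same <- snp_positions$chrom == tpos$chrom[i]
    d <- abs(snp_positions$pos - tpos$pos[i])
    hit <- same & d <= window_bp
    if (!any(hit)) return(NULL)
    data.frame(tsnp_id = tsnp_ids[i],
               dsnp_id = snp_positions$snp_id[hit],
               distance = d[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(tsnp_id = character(0), dsnp_id = character(0),
                      distance = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Fit the joint PO-ASE / ASE weighted regression for one dSNP-tSNP pair
#'
#' Fits, by weighted least squares with the total allele count T as weight
#' (the reciprocal of the error variance of the log ratio),
#' \deqn{y_i = \alpha + x_{1i} b_1 + e_i, \quad e \sim N(0, T^{-1}\sigma^2_e)}
#' where \eqn{y_i = \log_{10}(\mathrm{maternal}/\mathrm{paternal})} and
#' \eqn{x_1 \in \{-1,0,+1\}} is the phased driver coding of [code_dsnp()].
#' The intercept \eqn{\alpha} measures a parent-of-origin effect (partial
#' imprinting); the slope \eqn{b_1} measures cis-driven ASE. Two-sided
#' t-tests use n - 2 degrees of freedom (n - 1 when `x1` is constant, in
#' which case `b1` is not estimable and returned as `NA`).
#'
#' @param y Numeric vector of log10 maternal/paternal count ratios.
#' @param x1 Driver coding in \{-1, 0, +1\}.
#' @param weight Positive weights (total allele counts T).
#' @param min_n Minimum rows for a fit (default 3, so the residual variance
#'   has at least one degree of freedom); below it the pair is skipped.
#' @return One-row data.frame with `n`, `alpha`, `se_alpha`, `p_alpha`,
#'   `b1`, `se_b1`, `p_b1`, `sigma2_e_hat`; `NULL` when `n < min_n`.
#' @export
fit_ase_model <- function(y, x1, weight, min_n = 3) {
  n <- length(y)
  stopifnot(length(x1) == n, length(weight) == n, all(weight > 0),
            all(is.finite(y)))
  if (n < min_n) return(NULL)
  slope_estimable <- length(unique(x1)) > 1
  if (slope_estimable) {
    fit <- stats::lm(y ~ x1, weights = weight)
    df <- n - 2L
    cf <- summary(fit)$coefficients
    alpha <- cf["(Intercept)", 1]; se_a <- cf["(Intercept)", 2]
    b1 <- cf["x1", 1]; se_b <- cf["x1", 2]
    sigma2 <- sum(weight * stats::residuals(fit)^2) / df
    p_a <- 2 * stats::pt(abs(alpha / se_a), df, lower.tail = FALSE)
    p_b <- 2 * stats::pt(abs(b1 / se_b), df, lower.tail = FALSE)
  } else {
    fit <- stats::lm(y ~ 1, weights = weight)
    df <- n - 1L
    alpha <- stats::coef(fit)[[1]]
    se_a <- summary(fit)$coefficients[1, 2]
    sigma2 <- sum(weight * stats::residuals(fit)^2) / df
    p_a <- 2 * stats::pt(abs(alpha / se_a), df, lower.tail = FALSE)
    b1 <- NA_real_; se_b <- NA_real_; p_b <- NA_real_
  }
  data.frame(n = n, alpha = alpha, se_alpha = se_a, p_alpha = p_a,
             b1 = b1, se_b1 = se_b, p_b1 = p_b, sigma2_e_hat = sigma2,
             df = df)
}

#' Scan all dSNP-tSNP pairs for ASE and parent-of-origin effects
#'
#' End-to-end Eq.-1 analysis: filters counts to informative heterozygous
#' records, keeps tSNPs whose heterozygotes received opposite alleles from
#' their sires, enumerates candidate drivers within the window, and fits
#' the joint weighted regression per pair.
#'
#' @param counts `allele_counts` table.
#' @param genotypes `phased_genotypes` covering tSNPs and driver SNPs.
#' @param window_bp Pairing window (default 50000 bp).
#' @param min_coverage Coverage filter on T (strict `>`, default 10).
#' @param min_n Minimum informative rows per pair (default 3).
#' @return Data.frame of class `ase_results`: one row per fitted pair with
#'   the [fit_ase_model()] columns plus `tsnp_id`, `dsnp_id` and
#'   `effect_ref` (= `b1`; sign convention: positive means the reference
#'   allele increases expression). Attribute `n_skipped` counts pairs
#'   dropped for insufficient rows.
#' @export
ase_scan <- function(counts, genotypes, window_bp = 50000,
                     min_coverage = 10, min_n = 3) {
  filtered <- filter_informative_tsnps(counts, genotypes, min_coverage)
  by_tsnp <- split(filtered, filtered$tsnp_id)
  analyzable <- names(by_tsnp)[vapply(by_tsnp, tsnp_is_analyzable, logical(1))]
  snp_positions <- unique(data.frame(snp_id = genotypes$snp_id,
                                     chrom = genotypes$chrom,
                                     pos = genotypes$pos,
                                     stringsAsFactors = FALSE))
  if (length(analyzable) == 0) {
    res <- data.frame()
    attr(res, "n_skipped") <- 0L
    class(res) <- c("ase_results", "data.frame")
    return(res)
  }
  pairs <- enumerate_pairs(analyzable, snp_positions, window_bp)
  gkey <- paste(genotypes$animal_id, genotypes$snp_id)
  n_skipped <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rec <- by_tsnp[[pairs$tsnp_id[i]]]
    didx <- match(paste(rec$animal_id, pairs$dsnp_id[i]), gkey)
    has_d <- !is.na(didx)
    rec <- rec[has_d, , drop = FALSE]
    didx <- didx[has_d]
    if (nrow(rec) < min_n) { n_skipped <- n_skipped + 1L; next }
    x1 <- code_dsnp(genotypes$paternal_allele[didx],
                    genotypes$maternal_allele[didx])
    y <- log10(rec$maternal_count / rec$paternal_count)
    fit <- fit_ase_model(y, x1, rec$total, min_n = min_n)
    if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
    rows[[i]] <- cbind(data.frame(tsnp_id = pairs$tsnp_id[i],
                                  dsnp_id = pairs$dsnp_id[i],
                                  stringsAsFactors = FALSE), fit)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) res <- data.frame()
  if (nrow(res)) res$effect_ref <- res$b1
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("ase_results", "data.frame")
  res
}

#' Estimate the false discovery rate at a p-value threshold
#'
#' \deqn{FDR = \frac{P(1 - A/T)}{(A/T)(1 - P)}}
#' where `P` is the significance threshold, `A` the number of tests
#' significant at `P` and `T` the total number of tests. Equals 1 when
#' significance occurs exactly at the chance rate (`A = P T`) and decreases
#' as `A` grows.
#'
#' @param p_threshold Threshold `P` in (0, 1).
#' @param n_significant Number significant `A` (0 < A <= T; `A = 0` returns
#'   `NA` with a warning, the estimator being undefined there).
#' @param n_tests Total tests `T`.
#' @return FDR estimate (may exceed 1 when `A < P T`).
#' @export
compute_fdr <- function(p_threshold, n_significant, n_tests) {
  stopifnot(p_threshold > 0, p_threshold < 1, n_significant >= 0,
            n_tests > 0, n_significant <= n_tests)
  if (n_significant == 0) {
    warning("FDR undefined at A = 0")
    return(NA_real_)
  }
  rate <- n_significant / n_tests
  p_threshold * (1 - rate) / (rate * (1 - p_threshold))
}
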