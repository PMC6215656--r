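#' TMM normalization factors
#'
#' Per-sample scaling factors from the trimmed mean of M-values: the
#' reference sample is the one whose upper quartile is closest to the mean
#' upper quartile; each sample's factor is the inverse-variance-weighted
#' mean of its log2 expression ratios against the reference after trimming
#' the 30% most extreme M-values and 5% most extreme A-values,
#' exponentiated and rescaled so the factors have geometric mean 1
#' (computed via edgeR).
#'
#' @param counts Gene x sample count matrix (>= 2 samples).
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  if (any(colSums(counts) == 0)) {
    stop("sample with all-zero counts cannot be TMM-normalized")
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Normalize a gene count matrix to log10 counts-per-million
#'
#' Applies the expressed-gene filter (a gene is kept only when its count is
#' nonzero in strictly more than `min_expressed_frac` of animals), computes
#' TMM factors on the filtered matrix, converts to counts per million of
#' the TMM-adjusted library size, and returns
#' \eqn{y = \log_{10}(\mathrm{cpm} + \mathrm{offset})}. The +1 offset keeps
#' genes with residual zeros finite; genes passing the 25% filter can still
#' contain zeros.
#'
#' @param counts Gene x animal raw count matrix.
#' @param factors Optional precomputed TMM factors; computed when `NULL`.
#' @param min_expressed_frac Expressed-fraction filter, strict `>`
#'   (default 0.25).
#' @param offset Offset added to cpm before log10 (default 1).
#' @return List of class `normalized_expression`: `logcpm` (filtered gene x
#'   animal matrix of y values), `cpm`, `factors`, `lib_sizes`,
#'   `genes_dropped`.
#' @export
normalize_expression <- function(counts, factors = NULL,
                                 min_expressed_frac = 0.25, offset = 1) {
  expressed <- rowMeans(counts > 0) > min_expressed_frac
  kept <- counts[expressed, , drop = FALSE]
  if (is.null(factors)) factors <- tmm_factors(kept)
  lib <- colSums(kept)
  cpm <- sweep(kept, 2, lib * factors, "/") * 1e6
  structure(list(logcpm = log10(cpm + offset), cpm = cpm,
                 factors = factors, lib_sizes = lib,
                 genes_dropped = rownames(counts)[!expressed]),
            class = "normalized_expression")
}

#' Pedigree numerator relationship matrix
#'
#' Expected additive genetic relationships by the tabular method on a
#' topologically sorted pedigree: the diagonal is 1 plus half the
#' relationship between the animal's parents (inbreeding), and the
#' off-diagonal between animals j < i is the mean of j's relationships with
#' i's parents; unknown parents contribute 0.
#'
#' @param ped A [pedigree()].
#' @return Symmetric positive semidefinite matrix with dimnames =
#'   animal ids, diagonal >= 1.
#' @export
numerator_relationship_matrix <- function(ped) {
  ids <- ped$animal_id
  n <- length(ids)
  s <- match(ped$sire_id, ids)
  d <- match(ped$dam_id, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      a_s <- if (!is.na(s[i])) A[j, s[i]] else 0
      a_d <- if (!is.na(d[i])) A[j, d[i]] else 0
      A[j, i] <- A[i, j] <- 0.5 * (a_s + a_d)
    }
  }
  A
}

#' Fit the animal-model eQTL regression for one gene-SNP pair
#'
#' REML fit of
#' \deqn{y = 1\alpha + x_2 b_2 + u + e,\quad u \sim N(0, A\sigma^2_u),\;
#'       e \sim N(0, I\sigma^2_e)}
#' where y is log10 normalized expression and \eqn{x_2 \in \{0,1,2\}} is the
#' alternate-allele dose at the driver SNP (0 for a reference homozygote).
#' The variance ratio \eqn{\lambda = \sigma^2_u/\sigma^2_e} is profiled on
#' the restricted likelihood using the eigendecomposition of A, so each fit
#' is a one-dimensional deterministic optimization; \eqn{(\alpha, b_2)} are
#' the generalized-least-squares estimates at the REML variances. The
#' default test on \eqn{b_2} is a Wald z; `test = "t"` uses a t reference
#' with n - 2 df.
#'
#' @param y Expression vector (one gene, n animals).
#' @param x2 Alternate-allele dose in \{0, 1, 2\}.
#' @param A Relationship matrix restricted to (and ordered as) the n
#'   animals, or an `eigen()` decomposition of it (reused across genes).
#' @param test `"z"` (default) or `"t"`.
#' @return One-row data.frame `b2`, `se_b2`, `p_b2`, `alpha`,
#'   `sigma2_u_hat`, `sigma2_e_hat`, `n`, `converged`; `NULL` when `x2` is
#'   constant (effect inestimable).
#' @export
fit_eqtl <- function(y, x2, A, test = c("z", "t")) {
  test <- match.arg(test)
  n <- length(y)
  stopifnot(length(x2) == n)
  if (length(unique(x2)) < 2) return(NULL)
  eg <- if (is.list(A) && !is.null(A$vectors)) A else eigen(A, symmetric = TRUE)
  stopifnot(nrow(eg$vectors) == n)
  d <- pmax(eg$values, 0)
  X <- cbind(1, x2)
  yr <- crossprod(eg$vectors, y)
  Xr <- crossprod(eg$vectors, X)
  p <- ncol(X)

  # negative restricted log-likelihood, profiled over the scale sigma2_e
  nll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xr, w * Xr)
    beta <- solve(XtWX, crossprod(Xr, w * yr))
    r <- yr - Xr %*% beta
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    0.5 * (sum(log(lam * d + 1)) + determinant(XtWX)$modulus[1] +
             (n - p) * log(s2))
  }
  opt <- stats::optimize(nll, c(log(1e-8), log(1e8)), tol = 1e-8)
  # compare against the boundary lambda = 0 (no polygenic variance)
  lam <- exp(opt$minimum)
  if (nll(log(1e-12)) <= opt$objective + 1e-10) lam <- 0
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xr, w * Xr)
  beta <- solve(XtWX, crossprod(Xr, w * yr))
  r <- yr - Xr %*% beta
  sigma2_e <- sum(w * r^2) / (n - p)
  vcov_beta <- solve(XtWX) * sigma2_e
  b2 <- beta[2, 1]
  se_b2 <- sqrt(vcov_beta[2, 2])
  stat <- b2 / se_b2
  p_b2 <- if (test == "z") 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
    else 2 * stats::pt(abs(stat), n - p, lower.tail = FALSE)
  data.frame(b2 = b2, se_b2 = se_b2, p_b2 = p_b2, alpha = beta[1, 1],
             sigma2_u_hat = lam * sigma2_e, sigma2_e_hat = sigma2_e,
             n = n, converged = TRUE)
}

#' Scan genes for local eQTL
#'
#' Tests every SNP lying within `window_bp` of a gene's annotated span
#' (start - window .. end + window, inclusive) for association with the
#' gene's normalized expression under the pedigree animal model. The
#' relationship matrix is built once from the pedigree, restricted to the
#' expressed animals and eigendecomposed once; each gene-SNP pair is then a
#' one-dimensional REML fit.
#'
#' @param expr `normalized_expression` from [normalize_expression()]
#'   (columns = animal ids).
#' @param genotypes `phased_genotypes` for candidate driver SNPs.
#' @param annotation Gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param ped [pedigree()] covering the expressed animals; `NULL` treats
#'   animals as unrelated (A = I).
#' @param window_bp Window in bp (default 50000).
#' @param test Reference distribution for b2, `"z"` or `"t"`.
#' @return Data.frame of class `eqtl_results`: one row per tested gene-SNP
#'   pair with [fit_eqtl()] columns plus `gene_id`, `dsnp_id` and
#'   `effect_ref` (= `-b2`: re-oriented so positive means the reference
#'   allele increases expression, matching the ASE sign convention).
#' @export
eqtl_scan <- function(expr, genotypes, annotation, ped = NULL,
                      window_bp = 50000, test = "z") {
  y_mat <- expr$logcpm
  animals <- colnames(y_mat)
  if (is.null(ped)) {
    A_obs <- diag(length(animals))
    dimnames(A_obs) <- list(animals, animals)
  } else {
    A <- numerator_relationship_matrix(ped)
    stopifnot(all(animals %in% rownames(A)))
    A_obs <- A[animals, animals]
  }
  eg <- eigen(A_obs, symmetric = TRUE)
  snp_positions <- unique(data.frame(snp_id = genotypes$snp_id,
                                     chrom = genotypes$chrom,
                                     pos = genotypes$pos,
                                     stringsAsFactors = FALSE))
  gkey <- paste(genotypes$animal_id, genotypes$snp_id)
  dose <- genotypes$paternal_allele + genotypes$maternal_allele
  rows <- list()
  for (g in intersect(rownames(y_mat), annotation$gene_id)) {
    ann <- annotation[annotation$gene_id == g, ][1, ]
    hit <- snp_positions$chrom == ann$chrom &
      snp_positions$pos >= ann$start - window_bp &
      snp_positions$pos <= ann$end + window_bp
    for (snp in snp_positions$snp_id[hit]) {
      x2 <- dose[match(paste(animals, snp), gkey)]
      if (anyNA(x2)) next
      fit <- fit_eqtl(y_mat[g, ], x2, eg, test = test)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(gene_id = g, dsnp_id = snp,
                         stringsAsFactors = FALSE), fit)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(res)) res$effect_ref <- -res$b2
  rownames(res) <- NULL
  class(res) <- c("eqtl_results", "data.frame")
  res
}
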