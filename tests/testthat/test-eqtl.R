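# Minimal independent TMM implementation used as the oracle: reference =
# column with upper quartile closest to the mean upper quartile; factor =
# weighted mean of log2 ratios after trimming 30% of M and 5% of A values;
# factors rescaled to geometric mean 1.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    ok <- counts[, j] > 0 & counts[, ref] > 0
    pj <- counts[ok, j] / lib[j]; pr <- counts[ok, ref] / lib[ref]
    M <- log2(pj / pr); A <- 0.5 * log2(pj * pr)
    w <- (1 - counts[ok, j] / lib[j]) / counts[ok, j] +
      (1 - counts[ok, ref] / lib[ref]) / counts[ok, ref]
    keepM <- rank(M) > 0.3 * length(M) & rank(M) <= 0.7 * length(M)
    keepA <- rank(A) > 0.05 * length(A) & rank(A) <= 0.95 * length(A)
    keep <- keepM & keepA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

test_that("identical libraries give unit TMM factors", {
  m <- matrix(rep(c(10L, 50L, 200L, 5L), 4), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("a", 1:4)))
  expect_equal(unname(tmm_factors(m)), rep(1, 4))
})

test_that("TMM factors have geometric mean 1 and match an independent
           implementation on a doubled library", {
  set.seed(31)
  m <- matrix(rnbinom(400, mu = 100, size = 3) + 1L, 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("a", 1:4)))
  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # doubling every count of one sample is pure depth, not composition:
  # TMM factors should stay 1 for both samples of a two-sample matrix
  m2 <- cbind(a = m[, 1], b = 2L * m[, 1])
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-8)
  expect_equal(unname(f2), unname(tmm_oracle(m2)), tolerance = 1e-6)
  expect_error(tmm_factors(cbind(m[, 1], 0L)), "all-zero")
})

test_that("cpm is depth-invariant and the expressed filter is strict", {
  m <- matrix(c(100L, 0L, 200L, 0L, 300L, 0L, 400L, 1L), 2, 4,
              dimnames = list(c("on", "off"), paste0("a", 1:4)))
  # "off" is expressed in exactly 25% of animals -> dropped (strict >)
  ne <- normalize_expression(m, factors = rep(1, 4))
  expect_equal(rownames(ne$logcpm), "on")
  expect_equal(ne$genes_dropped, "off")
  # count 100 in a library of 1e6 at factor 1 -> 100 cpm
  big <- matrix(c(100L, 999900L), 2, 1)
  cpm <- sweep(big, 2, colSums(big) * 1, "/") * 1e6
  expect_equal(cpm[1, 1], 100)
  # doubling counts and library sizes leaves cpm unchanged
  m4 <- m * 2L
  ne4 <- normalize_expression(m4, factors = rep(1, 4))
  expect_equal(ne4$cpm, ne$cpm, ignore_attr = TRUE)
})

test_that("relationship matrix reproduces textbook values", {
  A1 <- numerator_relationship_matrix(pedigree(c("a", "b", "c"),
                                               NA, NA))
  expect_equal(unname(A1), diag(3))

  ped <- family_pedigree()
  A <- numerator_relationship_matrix(ped)
  expect_equal(A["s", "o1"], 0.5)     # parent-offspring
  expect_equal(A["o1", "o2"], 0.5)    # full sibs, unrelated parents
  expect_equal(unname(diag(A)), rep(1, 4))

  # offspring of half sibs: diagonal 1 + 0.5 * 0.25 = 1.125
  ped2 <- pedigree(c("s", "d1", "d2", "h1", "h2", "x"),
                   c(NA, NA, NA, "s", "s", "h1"),
                   c(NA, NA, NA, "d1", "d2", "h2"))
  A2 <- numerator_relationship_matrix(ped2)
  expect_equal(A2["h1", "h2"], 0.25)
  expect_equal(A2["x", "x"], 1.125)
})

test_that("relationship matrices are symmetric PSD on simulated pedigrees", {
  for (s in 1:5) {
    ped <- simulate_pedigree(8, 3, family_size = 2, seed = s)
    A <- numerator_relationship_matrix(ped)
    expect_equal(A, t(A))
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    expect_true(all(diag(A) >= 1))
  }
})

test_that("the animal model with no polygenic variance equals OLS", {
  set.seed(41)
  n <- 50
  x2 <- sample(0:2, n, replace = TRUE)
  y <- 1 + 0.3 * x2 + rnorm(n, 0, 0.2)
  fit <- fit_eqtl(y, x2, diag(n))
  ols <- summary(lm(y ~ x2))$coefficients
  # A = I makes u and e indistinguishable; only their sum is identified,
  # and the GLS point estimate equals OLS for any split
  expect_equal(fit$b2, ols[2, 1], tolerance = 1e-6)
  expect_equal(fit$sigma2_u_hat + fit$sigma2_e_hat,
               sum(resid(lm(y ~ x2))^2) / (n - 2), tolerance = 1e-4)
  expect_null(fit_eqtl(y, rep(1, n), diag(n)))
})

test_that("REML recovers the variance partition on a large pedigree", {
  set.seed(43)
  ped <- simulate_pedigree(100, 1, family_size = 4, seed = 43)
  A <- numerator_relationship_matrix(ped)
  n <- nrow(A)
  L <- t(chol(A))
  s2u <- 0.4; s2e <- 0.1
  x2 <- sample(0:2, n, replace = TRUE)
  y <- 2 + 0.25 * x2 + as.vector(L %*% rnorm(n)) * sqrt(s2u) +
    rnorm(n, 0, sqrt(s2e))
  fit <- fit_eqtl(y, x2, A)
  expect_equal(fit$b2, 0.25, tolerance = 0.1)
  expect_equal(fit$sigma2_u_hat / fit$sigma2_e_hat, s2u / s2e,
               tolerance = 0.75)
  expect_gt(fit$sigma2_u_hat, fit$sigma2_e_hat)
})

test_that("the eQTL scan tests SNPs within 50 kb of the gene span,
           boundary inclusive", {
  ped <- pedigree(paste0("a", 1:40), NA, NA)
  layout <- data.frame(
    snp_id = c("at_edge", "inside", "beyond"),
    chrom = "1", pos = c(50000L, 120000L, 170001L))
  gt <- simulate_phased_genotypes(ped, layout, maf = 0.4, seed = 51)
  ann <- data.frame(gene_id = "g1", chrom = "1",
                    start = 100000L, end = 120000L)
  counts <- simulate_gene_counts(gt, NULL, data.frame(gene_id = "g1",
                                                      dsnp_id = "inside"),
                                 b2_true = 0.3, sigma2_u = 0, seed = 52)
  counts <- rbind(counts, filler = rep(100L, ncol(counts)))
  rownames(counts) <- c("g1", "filler")
  expr <- normalize_expression(counts)
  res <- eqtl_scan(expr, gt, ann, ped = NULL)
  expect_setequal(res$dsnp_id, c("at_edge", "inside"))
  expect_equal(res$effect_ref, -res$b2)
})
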