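test_that("signed overlap statistic matches the 2x2 oracle in magnitude
           with the enrichment sign rule", {
  set.seed(81)
  for (i in 1:30) {
    n <- 500
    x <- runif(n) < 0.1
    y <- runif(n) < 0.15
    s <- signed_overlap_chi2(x, y)
    tab <- table(factor(x, c(TRUE, FALSE)), factor(y, c(TRUE, FALSE)))
    expect_equal(abs(s), chi2_2x2(unclass(tab))$statistic,
                 tolerance = 1e-10)
    expected <- sum(x) * sum(y) / n
    expect_equal(sign(s), sign(sum(x & y) - expected))
  }
  expect_warning(out <- signed_overlap_chi2(rep(TRUE, 20),
                                            rep(c(TRUE, FALSE), 10)),
                 "degenerate")
  expect_true(is.na(out))
})

test_that("overlap below expectation is negative; at expectation zero", {
  # margins 10/10 of 100 -> expected joint = 1; observed 0 -> impoverished
  x <- c(rep(TRUE, 10), rep(FALSE, 90))
  y <- c(rep(FALSE, 90), rep(TRUE, 10))
  expect_lt(signed_overlap_chi2(x, y), 0)
  # block design with joint count exactly at independence
  x2 <- rep(c(TRUE, FALSE), c(50, 50))
  y2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(25, 25, 25, 25))
  expect_equal(signed_overlap_chi2(x2, y2), 0)
})

test_that("circular shifts preserve both margins, hence every permuted
           table's margins equal the observed ones", {
  set.seed(83)
  n <- 1000
  x <- runif(n) < 0.05
  y <- runif(n) < 0.08
  null <- permutation_null(x, y, n_perm = 200, seed = 1)
  for (s in null$shifts[1:20]) {
    rot <- x[((seq_len(n) - s - 1) %% n) + 1]
    expect_equal(sum(rot), sum(x))
    # statistic recomputed on the brute-force rotated vector agrees
    expect_equal(signed_overlap_chi2(rot, y),
                 null$stats[which(null$shifts == s)[1]])
  }
})

test_that("permutation thresholds are the rank-based order statistics", {
  set.seed(85)
  x <- runif(2000) < 0.05
  y <- runif(2000) < 0.05
  null <- permutation_null(x, y, n_perm = 1000, seed = 2)
  sorted <- sort(null$stats)
  expect_equal(null$upper, sorted[950])
  expect_equal(null$lower, sorted[50])
  expect_identical(permutation_null(x, y, n_perm = 100, seed = 9)$stats,
                   permutation_null(x, y, n_perm = 100, seed = 9)$stats)
  expect_error(permutation_null(x, y, shift_range = c(0.5, 0.4)), "empty")
})

test_that("an all-zero eQTL vector degenerates to NA statistics", {
  x <- runif(100) < 0.2
  expect_warning(s <- signed_overlap_chi2(x, rep(FALSE, 100)), "degenerate")
  expect_true(is.na(s))
})

test_that("enrichment declaration uses strict inequality, one-tailed", {
  null <- structure(list(stats = numeric(0), upper = 6, lower = -10,
                         n_perm = 0, shifts = integer(0)),
                    class = "signed_chi2_null")
  expect_equal(enrichment_test(7, null), "significant_enrichment")
  expect_equal(enrichment_test(6, null), "neither")      # boundary
  expect_equal(enrichment_test(-12, null), "significant_impoverishment")
  expect_equal(enrichment_test(0, null), "neither")
})

test_that("strongly injected overlap is declared enriched", {
  set.seed(87)
  n <- 5000
  pos <- data.frame(snp_id = paste0("s", 1:n), chrom = "1",
                    pos = 1:n * 100L)
  eqtl_sig <- runif(n) < 0.02
  g <- simulate_gwas(pos, eqtls <- pos$snp_id[eqtl_sig],
                     overlap_prob = 0.5, background_rate = 0.01, seed = 88)
  qtl_sig <- g$significant[match(pos$snp_id, g$snp_id)]
  obs <- signed_overlap_chi2(qtl_sig, eqtl_sig)
  null <- permutation_null(qtl_sig, eqtl_sig, n_perm = 500, seed = 89)
  expect_equal(enrichment_test(obs, null), "significant_enrichment")
})

test_that("per-gene tables require a QTL and an eQTL and match the oracle", {
  pos <- data.frame(snp_id = paste0("s", 1:40), chrom = "1",
                    pos = seq(1000, 400000, length.out = 40))
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                    start = c(1L, 300000L), end = c(100000L, 310000L))
  qtl <- pos$pos < 60000            # QTL only near gA
  eqtl <- pos$pos < 30000
  res <- per_gene_overlap(pos, qtl, eqtl, ann, window_bp = 50000)
  expect_equal(res$gene_id, "gA")   # gB has no significant SNP at all
  in_a <- pos$pos >= ann$start[1] - 50000 & pos$pos <= ann$end[1] + 50000
  tab <- table(factor(qtl[in_a], c(TRUE, FALSE)),
               factor(eqtl[in_a], c(TRUE, FALSE)))
  expect_equal(res$chi2, chi2_2x2(unclass(tab))$statistic)
})

test_that("the gene-adjusted model matches the least-squares oracle and
           its exact-overlap reduction", {
  set.seed(91)
  for (i in 1:20) {
    n <- 200
    gene <- sample(paste0("g", 1:5), n, replace = TRUE)
    x4 <- rbinom(n, 1, 0.2)
    y <- rbinom(n, 1, 0.1 + 0.2 * x4)
    fit <- fit_gene_adjusted_model(y, gene, x4)
    X <- cbind(1, model.matrix(~ factor(gene))[, -1, drop = FALSE], x4)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(fit$b4, as.numeric(beta[nrow(beta), 1]), tolerance = 1e-8)
    expect_equal(fit$alpha, as.numeric(beta[1, 1]), tolerance = 1e-8)
  }
  # y = x4 exactly within a single gene: slope 1, zero residuals
  y <- c(0, 0, 1, 1, 0, 1)
  # perfect fit: lm warns that the summary is unreliable, which is the point
  fit <- suppressWarnings(fit_gene_adjusted_model(y, rep("g1", 6), y))
  expect_equal(fit$b4, 1)
  expect_equal(fit$p_one_sided, 0)
  expect_warning(out <- fit_gene_adjusted_model(y, rep("g1", 6),
                                                rep(1, 6)), "inestimable")
  expect_true(is.na(out$b4))
})

test_that("b4 is null-calibrated when eQTL status is independent of QTL
           status within genes", {
  set.seed(93)
  p1 <- replicate(200, {
    n <- 300
    gene <- sample(paste0("g", 1:6), n, replace = TRUE)
    fit <- fit_gene_adjusted_model(rbinom(n, 1, 0.2), gene,
                                   rbinom(n, 1, 0.2))
    fit$p_one_sided
  })
  expect_lt(abs(mean(p1 < 0.1) - 0.1), 0.06)
})

test_that("SNPs are assigned to their nearest gene with stable ties", {
  pos <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                    pos = c(150000L, 149999L, 400000L))
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                    start = c(90000L, 200000L), end = c(100000L, 210000L))
  g <- assign_snps_to_genes(pos, ann, window_bp = 50000)
  expect_equal(g, c("g1", "g1", NA))  # a: tie at 50kb -> smaller id
})
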