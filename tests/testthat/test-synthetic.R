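test_that("simulated pedigrees have the requested family structure", {
  ped <- simulate_pedigree(2, 1, family_size = 2, seed = 1)
  expect_equal(nrow(ped), 4L)
  kids <- ped[!is.na(ped$sire_id), ]
  expect_equal(nrow(kids), 2L)
  expect_equal(kids$sire_id[1], kids$sire_id[2])  # full sibs
  expect_equal(kids$dam_id[1], kids$dam_id[2])

  expect_equal(nrow(simulate_pedigree(5, 0, seed = 1)), 5L)
  expect_error(simulate_pedigree(1, 1), "founders")
  expect_identical(simulate_pedigree(10, 2, 3, seed = 42),
                   simulate_pedigree(10, 2, 3, seed = 42))
})

test_that("founder allele frequency matches the binomial draw", {
  layout <- data.frame(snp_id = paste0("s", 1:100), chrom = "1",
                       pos = 1:100 * 1000L)
  ped <- pedigree(paste0("F", 1:50), NA, NA)
  gt <- simulate_phased_genotypes(ped, layout, maf = 0.5, seed = 3)
  # 50 animals x 100 SNPs x 2 haplotypes = 10,000 founder haplotypes
  freq <- mean(c(gt$paternal_allele, gt$maternal_allele))
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("gene drop is Mendelian and maf = 0 gives all-reference", {
  layout <- data.frame(snp_id = paste0("s", 1:20), chrom = "1",
                       pos = 1:20 * 1000L, block = rep(c("b1", "b2"), 10))
  ped <- simulate_pedigree(10, 2, family_size = 2, seed = 5)
  gt <- simulate_phased_genotypes(ped, layout, maf = 0.4, seed = 5)
  ids <- ped$animal_id
  key <- paste(gt$animal_id, gt$snp_id)
  for (i in which(!is.na(ped$dam_id))) {
    kid <- gt[gt$animal_id == ids[i], ]
    dam <- gt[gt$animal_id == ped$dam_id[i], ]
    sire <- gt[gt$animal_id == ped$sire_id[i], ]
    dam <- dam[match(kid$snp_id, dam$snp_id), ]
    sire <- sire[match(kid$snp_id, sire$snp_id), ]
    expect_true(all(kid$maternal_allele == dam$paternal_allele |
                      kid$maternal_allele == dam$maternal_allele))
    expect_true(all(kid$paternal_allele == sire$paternal_allele |
                      kid$paternal_allele == sire$maternal_allele))
  }
  gt0 <- simulate_phased_genotypes(ped, layout, maf = 0, seed = 5)
  expect_true(all(gt0$paternal_allele == 0 & gt0$maternal_allele == 0))
})

test_that("null allelic counts are symmetric and depths respect the filter", {
  gt <- pair_genotypes(200)
  pair <- data.frame(tsnp_id = "tsnp", dsnp_id = "dsnp")
  cnt <- simulate_allele_counts(gt, pair, alpha_true = 0, b1_true = 0,
                                depth_mean = 50, seed = 11)
  # depths truncated so every record passes coverage > 10
  expect_true(all(cnt$total >= 11))
  expect_true(all(cnt$maternal_count >= 1 & cnt$paternal_count >= 1))
  # replicate draws to assess the null mean of the log ratio
  y <- unlist(lapply(1:50, function(i) {
    cc <- simulate_allele_counts(gt, pair, 0, 0, depth_mean = 50, seed = i)
    log10(cc$maternal_count / cc$paternal_count)
  }))
  expect_lt(abs(mean(y)), 3 * sd(y) / sqrt(length(y)))
})

test_that("a pure parent-of-origin effect shifts the maternal fraction to
           its closed-form value", {
  gt <- pair_genotypes(300)
  gt$paternal_allele[gt$snp_id == "dsnp"] <- 0L   # x1 = 0 everywhere
  gt$maternal_allele[gt$snp_id == "dsnp"] <- 0L
  cnt <- simulate_allele_counts(gt, data.frame(tsnp_id = "tsnp",
                                               dsnp_id = "dsnp"),
                                alpha_true = 0.3, b1_true = 0,
                                depth_mean = 200, seed = 2)
  expect_true(all(cnt$x1_true == 0))
  frac <- sum(cnt$maternal_count) / sum(cnt$total)
  expect_equal(frac, 10^0.3 / (1 + 10^0.3), tolerance = 0.02)
})

test_that("untruncated depths exercise the coverage filter", {
  gt <- pair_genotypes(500)
  cnt <- simulate_allele_counts(gt, data.frame(tsnp_id = "tsnp",
                                               dsnp_id = "dsnp"),
                                depth_mean = 12, depth_dispersion = 2,
                                truncate = FALSE, seed = 9)
  expect_gt(sum(cnt$total <= 10), 0)
  kept <- filter_informative_tsnps(cnt[setdiff(names(cnt), "x1_true")], gt)
  expect_true(all(kept$total > 10))
})

test_that("allele and gene count generators are seed-deterministic", {
  gt <- pair_genotypes(30)
  pair <- data.frame(tsnp_id = "tsnp", dsnp_id = "dsnp")
  expect_identical(simulate_allele_counts(gt, pair, 0.1, 0.2, seed = 4),
                   simulate_allele_counts(gt, pair, 0.1, 0.2, seed = 4))
  ped <- family_pedigree()
  g2 <- toy_genotypes(
    list(s = list(m = c(0L, 1L)), d = list(m = c(1L, 0L)),
         o1 = list(m = c(0L, 0L)), o2 = list(m = c(1L, 1L))),
    pos = c(m = 100L))
  gd <- data.frame(gene_id = "g1", dsnp_id = "m")
  expect_identical(
    simulate_gene_counts(g2, ped, gd, b2_true = 0.2, seed = 8),
    simulate_gene_counts(g2, ped, gd, b2_true = 0.2, seed = 8))
})

test_that("polygenic gene counts correlate within families", {
  ped <- simulate_pedigree(60, 1, family_size = 2, seed = 21)
  layout <- data.frame(snp_id = "snp1", chrom = "1", pos = 1000L)
  gt <- simulate_phased_genotypes(ped, layout, maf = 0.3, seed = 21)
  gd <- data.frame(gene_id = paste0("g", 1:300), dsnp_id = "snp1")
  cnt <- simulate_gene_counts(gt, ped, gd, b2_true = 0,
                              sigma2_u = 0.05, sigma2_e = 0.005,
                              seed = 22)
  y <- log10(cnt + 1)
  kids <- ped$animal_id[!is.na(ped$sire_id)]
  sib1 <- kids[seq(1, length(kids), 2)]
  sib2 <- kids[seq(2, length(kids), 2)]
  r_sib <- mean(vapply(seq_along(sib1), function(i)
    cor(y[, sib1[i]], y[, sib2[i]]), numeric(1)))
  unrel <- cor(y[, "F1"], y[, "F2"])
  # full sibs share half the polygenic variance; founders none
  expect_gt(r_sib, 0.25)
  expect_lt(abs(unrel), 0.2)
})

test_that("simulated GWAS overlap behaves at the extremes and under
           independence", {
  pos <- data.frame(snp_id = paste0("s", 1:2000), chrom = "1",
                    pos = 1:2000 * 100L)
  eqtls <- paste0("s", 1:200)
  g1 <- simulate_gwas(pos, eqtls, overlap_prob = 1, background_rate = 0,
                      seed = 6)
  expect_true(all(g1$significant[g1$snp_id %in% eqtls]))
  expect_true(!any(g1$significant[!g1$snp_id %in% eqtls]))
  expect_identical(simulate_gwas(pos, eqtls, 0.3, seed = 7),
                   simulate_gwas(pos, eqtls, 0.3, seed = 7))
  expect_error(simulate_gwas(pos, eqtls, overlap_prob = 1.2), "overlap_prob")

  # overlap probability equal to the background rate = independence
  folds <- vapply(1:40, function(i) {
    g <- simulate_gwas(pos, eqtls, overlap_prob = 0.2,
                       background_rate = 0.2, seed = i)
    sig <- g$significant[match(pos$snp_id, g$snp_id)]
    is_e <- pos$snp_id %in% eqtls
    (sum(sig & is_e) / length(sig)) /
      (mean(sig) * mean(is_e))
  }, numeric(1))
  expect_equal(mean(folds), 1, tolerance = 0.1)
})

test_that("simulated datasets are byte-identical under a fixed seed", {
  b1 <- simulate_dataset(sim_config(seed = 33L, n_genes = 3))
  b2 <- simulate_dataset(sim_config(seed = 33L, n_genes = 3))
  expect_identical(b1, b2)
})
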