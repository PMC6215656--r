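# Small in-code fixtures shared across test files.

# 4-animal nuclear family: two unrelated founders, two full-sib offspring.
family_pedigree <- function() {
  pedigree(c("s", "d", "o1", "o2"),
           c(NA, NA, "s", "s"),
           c(NA, NA, "d", "d"))
}

# Phased genotype table from a named list of c(paternal, maternal) pairs:
# toy_genotypes(list(a1 = list(snp1 = c(0, 1))), pos = c(snp1 = 100))
toy_genotypes <- function(animal_snps, pos, chrom = "1") {
  rows <- do.call(rbind, lapply(names(animal_snps), function(an) {
    snps <- animal_snps[[an]]
    data.frame(animal_id = an, snp_id = names(snps), chrom = chrom,
               pos = unname(pos[names(snps)]),
               paternal_allele = vapply(snps, `[`, 0, 1),
               maternal_allele = vapply(snps, `[`, 0, 2),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  aseqtl:::validate_phased_genotypes(rows)
}

# Independent weighted-least-squares oracle: solves the 2x2 normal
# equations (X'WX) beta = X'Wy directly.
wls_oracle <- function(y, x, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  r <- y - X %*% beta
  df <- length(y) - 2
  s2 <- sum(w * r^2) / df
  se <- sqrt(diag(solve(XtWX)) * s2)
  list(alpha = as.numeric(beta[1, 1]), b1 = as.numeric(beta[2, 1]),
       se_alpha = as.numeric(se[1]), se_b1 = as.numeric(se[2]), sigma2 = s2)
}

# Genotypes for one dSNP-tSNP pair with guaranteed x1 variation: half the
# heterozygotes get the reference allele from the sire, half from the dam,
# and a third of animals are homozygous at the driver.
pair_genotypes <- function(n_animals) {
  ids <- paste0("a", seq_len(n_animals))
  third <- ceiling(n_animals / 3)
  pat_d <- rep(c(0L, 1L, 0L), length.out = n_animals)
  mat_d <- rep(c(1L, 0L, 0L), length.out = n_animals)
  out <- rbind(
    data.frame(animal_id = ids, snp_id = "tsnp", chrom = "1", pos = 1000L,
               paternal_allele = rep(c(0L, 1L), length.out = n_animals),
               maternal_allele = rep(c(1L, 0L), length.out = n_animals)),
    data.frame(animal_id = ids, snp_id = "dsnp", chrom = "1", pos = 2000L,
               paternal_allele = pat_d, maternal_allele = mat_d)
  )
  aseqtl:::validate_phased_genotypes(out)
}

# One simulated ASE design + fit at given truth; returns the fit row.
simulate_and_fit_pair <- function(n_animals, alpha_true, b1_true,
                                  depth_mean = 100) {
  gt <- pair_genotypes(n_animals)
  cnt <- simulate_allele_counts(
    gt, data.frame(tsnp_id = "tsnp", dsnp_id = "dsnp"),
    alpha_true = alpha_true, b1_true = b1_true, depth_mean = depth_mean
  )
  fit_ase_model(log10(cnt$maternal_count / cnt$paternal_count),
                cnt$x1_true, cnt$total)
}
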