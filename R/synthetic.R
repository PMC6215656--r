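#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; in each later generation,
#' the previous generation's animals are paired at random into couples and
#' every couple produces `family_size` offspring. This yields full-sib
#' families and across-generation relationships, enough structure to
#' exercise the numerator relationship matrix and the polygenic term of the
#' animal model.
#'
#' @param n_founders Number of founders (>= 2, even numbers pair fully).
#' @param n_generations Number of offspring generations (0 = founders only).
#' @param family_size Offspring per couple (default 2).
#' @param seed Optional integer seed.
#' @return A [pedigree()] with ids `F<i>` for founders and
#'   `G<g>_<k>` for generation-g offspring.
#' @export
simulate_pedigree <- function(n_founders, n_generations, family_size = 2,
                              seed = NULL) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("F", seq_len(n_founders))
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  prev <- ids
  for (g in seq_len(n_generations)) {
    shuffled <- sample(prev)
    n_couples <- length(shuffled) %/% 2
    kids <- paste0("G", g, "_", seq_len(n_couples * family_size))
    ids <- c(ids, kids)
    sire <- c(sire, rep(shuffled[seq_len(n_couples) * 2 - 1],
                        each = family_size))
    dam <- c(dam, rep(shuffled[seq_len(n_couples) * 2], each = family_size))
    prev <- kids
  }
  pedigree(ids, sire, dam)
}

#' Gene-drop simulation of phased genotypes through a pedigree
#'
#' Founder haplotype alleles are drawn Bernoulli(`maf`) per SNP; each
#' offspring inherits, from each parent, one of that parent's two
#' haplotypes. Transmission is per linkage block (`snp_layout$block`): all
#' SNPs in a block travel on the same inherited haplotype, so linkage
#' within a 50-kb gene window is complete — recombination at that scale is
#' negligible and is not modeled. Parental origin is recorded exactly.
#'
#' @param ped A [pedigree()].
#' @param snp_layout Data.frame `snp_id`, `chrom`, `pos` and optionally
#'   `block` (defaults to `chrom`).
#' @param maf Alternate-allele frequency in founders, scalar or per-SNP
#'   vector, in (0, 0.5] (0 gives an all-reference population).
#' @param seed Optional integer seed.
#' @return A `phased_genotypes` table covering every animal and SNP.
#' @export
simulate_phased_genotypes <- function(ped, snp_layout, maf = 0.3,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_snp <- nrow(snp_layout)
  maf <- rep_len(maf, n_snp)
  block <- factor(if (!is.null(snp_layout$block)) snp_layout$block
                  else snp_layout$chrom)
  ids <- ped$animal_id
  n <- length(ids)
  pat <- mat <- matrix(0L, n, n_snp, dimnames = list(ids, snp_layout$snp_id))
  s_idx <- match(ped$sire_id, ids)
  d_idx <- match(ped$dam_id, ids)
  for (i in seq_len(n)) {
    for (parent in c("sire", "dam")) {
      p_idx <- if (parent == "sire") s_idx[i] else d_idx[i]
      if (is.na(p_idx)) {
        hap <- as.integer(stats::rbinom(n_snp, 1L, maf))
      } else {
        # one Mendelian coin per linkage block, whole blocks transmitted
        take_pat <- stats::rbinom(nlevels(block), 1L, 0.5)[as.integer(block)]
        hap <- ifelse(take_pat == 1L, pat[p_idx, ], mat[p_idx, ])
      }
      if (parent == "sire") pat[i, ] <- hap else mat[i, ] <- hap
    }
  }
  out <- data.frame(
    animal_id = rep(ids, times = n_snp),
    snp_id = rep(snp_layout$snp_id, each = n),
    chrom = rep(as.character(snp_layout$chrom), each = n),
    pos = rep(snp_layout$pos, each = n),
    paternal_allele = as.integer(pat),
    maternal_allele = as.integer(mat),
    stringsAsFactors = FALSE
  )
  validate_phased_genotypes(out)
}

# Truncated negative-binomial depth draws (redraw until > min_total).
.rdepth <- function(n, depth_mean, depth_dispersion, min_total = 10) {
  out <- stats::rnbinom(n, mu = depth_mean, size = depth_dispersion)
  bad <- out <= min_total
  while (any(bad)) {
    out[bad] <- stats::rnbinom(sum(bad), mu = depth_mean,
                               size = depth_dispersion)
    bad <- out <= min_total
  }
  out
}

#' Simulate allele counts at transcript SNPs
#'
#' Generative mirror of the joint PO-ASE/ASE regression. For each animal
#' heterozygous at a tSNP, the total depth T is negative-binomial
#' (mean `depth_mean`, dispersion `depth_dispersion`), by default truncated
#' at T >= 11 so that simulated records pass the coverage filter by
#' construction, and the maternal count is Binomial(T, p) with
#' \deqn{p = r/(1+r),\qquad r = 10^{\alpha + b_1 x_1}}
#' where \eqn{x_1} is the [code_dsnp()] coding of the animal at the tSNP's
#' designated driver. The binomial noise gives the log ratio a variance
#' proportional to 1/T, matching the model's use of T as the weight.
#' Records that land on a zero count for either allele (which the
#' eligibility filter would discard) are redrawn.
#'
#' @param genotypes `phased_genotypes` covering the tSNPs and drivers.
#' @param tsnp_dsnp Data.frame `tsnp_id`, `dsnp_id`; optional per-row
#'   `alpha_true`, `b1_true` override the scalars.
#' @param alpha_true Parent-of-origin effect on the log10 ratio (default 0).
#' @param b1_true Cis driver effect on the log10 ratio (default 0).
#' @param depth_mean,depth_dispersion Negative-binomial depth parameters
#'   (defaults 100 and 5).
#' @param truncate Keep T > `min_coverage` by redrawing (default TRUE;
#'   FALSE emits untruncated depths so the coverage filter itself can be
#'   tested).
#' @param min_coverage Truncation bound (default 10).
#' @param seed Optional integer seed.
#' @return `allele_counts` table (one record per heterozygous animal x
#'   tSNP) with an `x1_true` column recording the driver coding used.
#' @export
simulate_allele_counts <- function(genotypes, tsnp_dsnp, alpha_true = 0,
                                   b1_true = 0, depth_mean = 100,
                                   depth_dispersion = 5, truncate = TRUE,
                                   min_coverage = 10, seed = NULL) {
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (!is.null(seed)) set.seed(seed)
  gkey <- paste(genotypes$animal_id, genotypes$snp_id)
  alpha <- if (!is.null(tsnp_dsnp$alpha_true)) tsnp_dsnp$alpha_true
    else rep(alpha_true, nrow(tsnp_dsnp))
  b1 <- if (!is.null(tsnp_dsnp$b1_true)) tsnp_dsnp$b1_true
    else rep(b1_true, nrow(tsnp_dsnp))
  rows <- vector("list", nrow(tsnp_dsnp))
  for (i in seq_len(nrow(tsnp_dsnp))) {
    t_rows <- genotypes[genotypes$snp_id == tsnp_dsnp$tsnp_id[i] &
                          genotypes$paternal_allele !=
                          genotypes$maternal_allele, , drop = FALSE]
    if (nrow(t_rows) == 0) next
    didx <- match(paste(t_rows$animal_id, tsnp_dsnp$dsnp_id[i]), gkey)
    x1 <- code_dsnp(genotypes$paternal_allele[didx],
                    genotypes$maternal_allele[didx])
    p <- 10^(alpha[i] + b1[i] * x1)
    p <- p / (1 + p)
    m <- nrow(t_rows)
    total <- .rdepth(m, depth_mean, depth_dispersion,
                     if (truncate) min_coverage else -1)
    mat <- stats::rbinom(m, total, p)
    # a zero count for either allele would be filtered; redraw those records
    # (untruncated draws are left as-is so the filters can be exercised)
    bad <- if (truncate) mat == 0 | mat == total else rep(FALSE, m)
    tries <- 0L
    while (any(bad) && tries < 1000L) {
      total[bad] <- .rdepth(sum(bad), depth_mean, depth_dispersion,
                            if (truncate) min_coverage else -1)
      mat[bad] <- stats::rbinom(sum(bad), total[bad], p[bad])
      bad <- mat == 0 | mat == total
      tries <- tries + 1L
    }
    rec <- allele_counts(t_rows$animal_id, tsnp_dsnp$tsnp_id[i],
                         mat, total - mat)
    rec$x1_true <- x1
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- allele_counts(character(0), character(0),
                                         numeric(0), numeric(0))
  rownames(out) <- NULL
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' Simulate a gene count matrix with an eQTL and a polygenic effect
#'
#' Latent log10 expression per gene and animal is
#' \deqn{\ell = \mu + b_2 x_2 + u + e,\quad u \sim MVN(0, A\sigma^2_u),\;
#'       e \sim N(0, \sigma^2_e)}
#' with \eqn{x_2} the alternate-allele dose at the gene's driver SNP and A
#' the pedigree relationship matrix; observed counts are
#' Poisson(\eqn{10^\ell \cdot s_i}) with per-animal library scaling
#' \eqn{s_i}.
#'
#' @param genotypes `phased_genotypes` (defines the animal set).
#' @param ped [pedigree()]; `NULL` for unrelated animals (A = I).
#' @param gene_dsnp Data.frame `gene_id`, `dsnp_id`; optional per-row
#'   `b2_true` overrides the scalar.
#' @param b2_true eQTL effect on log10 expression (default 0).
#' @param sigma2_u,sigma2_e Polygenic and residual variances (defaults
#'   0.05 each).
#' @param mu Baseline log10 expression (default 2, i.e. ~100 counts).
#' @param library_scaling Per-animal relative library size, recycled
#'   (default 1).
#' @param seed Optional integer seed.
#' @return Integer matrix genes x animals.
#' @export
simulate_gene_counts <- function(genotypes, ped, gene_dsnp, b2_true = 0,
                                 sigma2_u = 0.05, sigma2_e = 0.05, mu = 2,
                                 library_scaling = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  animals <- unique(genotypes$animal_id)
  n <- length(animals)
  scaling <- rep_len(library_scaling, n)
  if (is.null(ped) || sigma2_u == 0) {
    L <- NULL
  } else {
    A <- numerator_relationship_matrix(ped)[animals, animals]
    L <- t(chol(A))
  }
  gkey <- paste(genotypes$animal_id, genotypes$snp_id)
  dose <- genotypes$paternal_allele + genotypes$maternal_allele
  b2 <- if (!is.null(gene_dsnp$b2_true)) gene_dsnp$b2_true
    else rep(b2_true, nrow(gene_dsnp))
  counts <- matrix(0L, nrow(gene_dsnp), n,
                   dimnames = list(gene_dsnp$gene_id, animals))
  for (i in seq_len(nrow(gene_dsnp))) {
    x2 <- dose[match(paste(animals, gene_dsnp$dsnp_id[i]), gkey)]
    u <- if (is.null(L)) 0 else as.vector(L %*% stats::rnorm(n)) * sqrt(sigma2_u)
    latent <- mu + b2[i] * x2 + u + stats::rnorm(n, 0, sqrt(sigma2_e))
    counts[i, ] <- stats::rpois(n, 10^latent * scaling)
  }
  counts
}

#' Simulate a GWAS summary table with controllable eQTL overlap
#'
#' Assigns a significance indicator per SNP: a true-eQTL SNP is a QTL with
#' probability `overlap_prob`, any other SNP with the background rate
#' (optionally back-computed from a target significant count), then draws
#' p-values, effects and standard errors consistent with the indicators
#' (significant p uniform below the threshold, non-significant uniform
#' above; effect = z-equivalent of p times the SE, random sign).
#'
#' @param snp_positions Data.frame `snp_id`, `chrom`, `pos`.
#' @param eqtl_snps Character vector of SNP ids that are true eQTL.
#' @param overlap_prob Probability a true eQTL SNP is also a QTL, in
#'   \[0, 1\].
#' @param background_rate Significance rate for other SNPs (default 0.01).
#' @param n_sig_target Optional expected total significant count; overrides
#'   `background_rate`.
#' @param p_threshold Significance threshold used to place p-values
#'   (default 1e-3).
#' @param se SE scale for the effects (default 0.1).
#' @param trait_id Trait label (default "sim_trait").
#' @param seed Optional integer seed.
#' @return GWAS data.frame (`snp_id`, `chrom`, `pos`, `effect`, `se`,
#'   `p_value`, `trait_id`, `significant`) sorted by (chrom, pos).
#' @export
simulate_gwas <- function(snp_positions, eqtl_snps = character(0),
                          overlap_prob = 0.5, background_rate = 0.01,
                          n_sig_target = NULL, p_threshold = 1e-3,
                          se = 0.1, trait_id = "sim_trait", seed = NULL) {
  if (overlap_prob < 0 || overlap_prob > 1) {
    stop("overlap_prob must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(snp_positions)
  is_eqtl <- snp_positions$snp_id %in% eqtl_snps
  if (!is.null(n_sig_target)) {
    n_bg <- n - sum(is_eqtl)
    background_rate <- max(0, min(1,
      (n_sig_target - overlap_prob * sum(is_eqtl)) / max(n_bg, 1)))
  }
  sig <- stats::runif(n) < ifelse(is_eqtl, overlap_prob, background_rate)
  p <- ifelse(sig, stats::runif(n, 0, p_threshold),
              stats::runif(n, p_threshold, 1))
  z <- stats::qnorm(p / 2, lower.tail = FALSE) * sample(c(-1, 1), n, TRUE)
  out <- data.frame(snp_id = snp_positions$snp_id,
                    chrom = snp_positions$chrom, pos = snp_positions$pos,
                    effect = z * se, se = se, p_value = p,
                    trait_id = trait_id, significant = sig,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default simulation configuration
#'
#' Study conditions for the synthetic pipeline: a 100-animal pedigree
#' (40 founders, one offspring generation of 20 families of 3), 10 genes of
#' 10 kb spaced 200 kb apart on one chromosome (so 50-kb windows never
#' overlap), 2 tSNPs and 3 candidate driver SNPs per gene at founder MAF
#' 0.3, sequencing depth ~100x (negative-binomial dispersion 5),
#' parent-of-origin effect 0.2 and cis effect 0.3 on the log10 allelic
#' ratio, eQTL effect 0.25 on log10 expression with polygenic and residual
#' variances 0.05, and a 50% QTL/eQTL overlap probability over a 1%
#' background GWAS significance rate.
#'
#' @param ... Overrides for any field.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(n_founders = 40, n_generations = 1, family_size = 3,
              n_genes = 10, tsnps_per_gene = 2, dsnps_per_gene = 3,
              gene_length = 10000, gene_spacing = 200000, chrom = "1",
              maf = 0.3, alpha_true = 0.2, b1_true = 0.3,
              depth_mean = 100, depth_dispersion = 5,
              b2_true = 0.25, sigma2_u = 0.05, sigma2_e = 0.05, mu = 2,
              qtl_eqtl_overlap_prob = 0.5, gwas_background_rate = 0.01,
              window_bp = 50000, seed = 1L)
  override <- list(...)
  stopifnot(all(names(override) %in% names(cfg)))
  cfg[names(override)] <- override
  stopifnot(cfg$maf > 0, cfg$maf <= 0.5, cfg$sigma2_u >= 0,
            cfg$sigma2_e >= 0, cfg$qtl_eqtl_overlap_prob >= 0,
            cfg$qtl_eqtl_overlap_prob <= 1)
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate a complete input bundle
#'
#' Generates, under one seed, every input the pipeline consumes: pedigree,
#' genome layout (genes and SNPs), phased genotypes (gene-drop with whole
#' gene windows as linkage blocks), allele counts, gene counts and a GWAS
#' table, plus a truth table recording the generative parameters per gene.
#' Each gene gets `tsnps_per_gene` tSNPs inside its span and
#' `dsnps_per_gene` additional candidate drivers in its 50-kb window; the
#' first driver is the causal one for both the allelic and the expression
#' signal.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_bundle`: `config`, `pedigree`, `annotation`,
#'   `snp_layout`, `genotypes`, `allele_counts`, `gene_counts`, `gwas`,
#'   `truth` (per gene: causal dSNP, tSNPs, alpha/b1/b2 used).
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  ped <- simulate_pedigree(config$n_founders, config$n_generations,
                           config$family_size)
  genes <- data.frame(
    gene_id = sprintf("gene%02d", seq_len(config$n_genes)),
    chrom = config$chrom,
    start = (seq_len(config$n_genes) - 1L) * config$gene_spacing + 100001L,
    stringsAsFactors = FALSE
  )
  genes$end <- genes$start + config$gene_length - 1L

  snp_rows <- lapply(seq_len(config$n_genes), function(g) {
    tpos <- round(seq(genes$start[g], genes$end[g],
                      length.out = config$tsnps_per_gene + 2L))
    tpos <- tpos[-c(1L, length(tpos))]
    dpos <- genes$start[g] - round(seq(5000, config$window_bp - 5000,
                                       length.out = config$dsnps_per_gene))
    data.frame(
      snp_id = c(sprintf("g%02d_t%d", g, seq_along(tpos)),
                 sprintf("g%02d_d%d", g, seq_along(dpos))),
      chrom = config$chrom, pos = c(tpos, dpos),
      block = genes$gene_id[g],
      role = c(rep("tsnp", length(tpos)), rep("dsnp", length(dpos))),
      gene_id = genes$gene_id[g], stringsAsFactors = FALSE
    )
  })
  snp_layout <- do.call(rbind, snp_rows)
  snp_layout <- snp_layout[order(snp_layout$pos), , drop = FALSE]
  rownames(snp_layout) <- NULL

  genotypes <- simulate_phased_genotypes(ped, snp_layout, config$maf)

  tsnp_dsnp <- do.call(rbind, lapply(seq_len(config$n_genes), function(g) {
    data.frame(tsnp_id = sprintf("g%02d_t%d", g,
                                 seq_len(config$tsnps_per_gene)),
               dsnp_id = sprintf("g%02d_d1", g),
               gene_id = genes$gene_id[g], stringsAsFactors = FALSE)
  }))
  counts <- simulate_allele_counts(
    genotypes, tsnp_dsnp, alpha_true = config$alpha_true,
    b1_true = config$b1_true, depth_mean = config$depth_mean,
    depth_dispersion = config$depth_dispersion
  )
  gene_dsnp <- unique(tsnp_dsnp[c("gene_id", "dsnp_id")])
  gene_counts <- simulate_gene_counts(
    genotypes, ped, gene_dsnp, b2_true = config$b2_true,
    sigma2_u = config$sigma2_u, sigma2_e = config$sigma2_e, mu = config$mu
  )
  gwas <- simulate_gwas(
    snp_layout[c("snp_id", "chrom", "pos")],
    eqtl_snps = gene_dsnp$dsnp_id,
    overlap_prob = config$qtl_eqtl_overlap_prob,
    background_rate = config$gwas_background_rate
  )
  truth <- cbind(tsnp_dsnp,
                 alpha_true = config$alpha_true, b1_true = config$b1_true,
                 b2_true = config$b2_true)
  structure(list(config = config, pedigree = ped, annotation = genes,
                 snp_layout = snp_layout, genotypes = genotypes,
                 allele_counts = counts, gene_counts = gene_counts,
                 gwas = gwas, truth = truth),
            class = "sim_bundle")
}

#' Write a simulated bundle to disk as plain-text files
#'
#' @param bundle A `sim_bundle` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    allele_counts = file.path(dir, "allele_counts.tsv"),
    gene_counts = file.path(dir, "gene_counts.tsv"),
    annotation = file.path(dir, "genes.gff3"),
    pedigree = file.path(dir, "pedigree.tsv"),
    gwas = file.path(dir, "gwas.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_phased_genotypes(bundle$genotypes, paths["genotypes"])
  write_result_tsv(as.data.frame(bundle$allele_counts),
                   paths["allele_counts"])
  write_gene_counts(bundle$gene_counts, paths["gene_counts"])
  write_annotation(bundle$annotation, paths["annotation"], format = "gff3")
  write_pedigree(bundle$pedigree, paths["pedigree"])
  write_result_tsv(bundle$gwas[setdiff(names(bundle$gwas), "significant")],
                   paths["gwas"])
  write_result_tsv(bundle$truth, paths["truth"])
  paths
}
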