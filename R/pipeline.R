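#' Run the full synthetic-to-results pipeline
#'
#' Executes the stages in dependency order from a single configuration:
#' simulate the input bundle, write it to `out_dir/inputs`, run the ASE /
#' PO-ASE scan, the local eQTL scan, the signed-z meta-analysis of the two
#' (matched on dSNP + gene), the ASE-vs-eQTL significance cross-tabulation,
#' and the QTL-eQTL overlap tests (global permutation test, per-gene 2x2
#' tables, gene-adjusted linear model). Every output is a headered TSV
#' under `out_dir`; a JSON manifest records the seed, package version, row
#' counts and per-stage status. All randomness derives from the single
#' `seed` in `config`, so reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param out_dir Output directory.
#' @param p_threshold Significance threshold for comparisons and overlap
#'   tests (default 1e-3).
#' @param n_perm Permutation replicates for the overlap null
#'   (default 10000).
#' @return The manifest, invisibly (list with `files`, `counts`, `seed`,
#'   `version`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         p_threshold = 1e-3, n_perm = 10000) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("pipeline seed ", config$seed, ", aseqtl ",
          as.character(utils::packageVersion("aseqtl")))

  bundle <- simulate_dataset(config)
  input_files <- write_dataset(bundle, file.path(out_dir, "inputs"))

  ase <- ase_scan(bundle$allele_counts, bundle$genotypes,
                  window_bp = config$window_bp)
  ase$gene_id <- bundle$snp_layout$gene_id[
    match(ase$tsnp_id, bundle$snp_layout$snp_id)]
  write_result_tsv(ase, file.path(out_dir, "ase_results.tsv"))

  expr <- normalize_expression(bundle$gene_counts)
  eqtl <- eqtl_scan(expr, bundle$genotypes, bundle$annotation,
                    ped = bundle$pedigree, window_bp = config$window_bp)
  write_result_tsv(eqtl, file.path(out_dir, "eqtl_results.tsv"))

  ase_est <- data.frame(dsnp_id = ase$dsnp_id, gene_id = ase$gene_id,
                        effect = ase$effect_ref, se = ase$se_b1,
                        df = ase$df, p = ase$p_b1,
                        stringsAsFactors = FALSE)
  ase_est <- ase_est[!is.na(ase_est$effect), , drop = FALSE]
  eqtl_est <- data.frame(dsnp_id = eqtl$dsnp_id, gene_id = eqtl$gene_id,
                         effect = eqtl$effect_ref, se = eqtl$se_b2,
                         df = eqtl$n - 2, p = eqtl$p_b2,
                         stringsAsFactors = FALSE)
  meta <- meta_analyze(list(ase = ase_est, eqtl = eqtl_est),
                       by = c("dsnp_id", "gene_id"))
  write_result_tsv(meta, file.path(out_dir, "meta_results.tsv"))

  comparison <- crosstab(ase_est, eqtl_est, by = c("dsnp_id", "gene_id"),
                         p_threshold = p_threshold)
  write_result_tsv(comparison, file.path(out_dir, "ase_eqtl_overlap.tsv"))

  snp_pos <- bundle$snp_layout[c("snp_id", "chrom", "pos")]
  gwas_sig <- bundle$gwas$p_value[match(snp_pos$snp_id,
                                        bundle$gwas$snp_id)] < p_threshold
  best_eqtl_p <- tapply(eqtl$p_b2, eqtl$dsnp_id, min)
  eqtl_sig_vec <- rep(FALSE, nrow(snp_pos))
  hit <- match(names(best_eqtl_p), snp_pos$snp_id)
  eqtl_sig_vec[hit] <- best_eqtl_p < p_threshold

  observed <- signed_overlap_chi2(gwas_sig, eqtl_sig_vec)
  null <- permutation_null(gwas_sig, eqtl_sig_vec, n_perm = n_perm,
                           seed = config$seed + 1L)
  verdict <- enrichment_test(observed, null)
  global <- data.frame(observed_chi2 = observed, upper = null$upper,
                       lower = null$lower, n_perm = null$n_perm,
                       verdict = verdict)
  write_result_tsv(global, file.path(out_dir, "qtl_overlap_global.tsv"))
  write_result_tsv(data.frame(signed_chi2 = null$stats),
                   file.path(out_dir, "qtl_overlap_null.tsv"))

  per_gene <- per_gene_overlap(snp_pos, gwas_sig, eqtl_sig_vec,
                               bundle$annotation, config$window_bp)
  write_result_tsv(per_gene, file.path(out_dir, "qtl_overlap_per_gene.tsv"))

  gene_of <- assign_snps_to_genes(snp_pos, bundle$annotation,
                                  config$window_bp)
  in_gene <- !is.na(gene_of)
  fit5 <- fit_gene_adjusted_model(eqtl_sig_vec[in_gene], gene_of[in_gene],
                                  gwas_sig[in_gene])
  write_result_tsv(data.frame(b4 = fit5$b4, se_b4 = fit5$se_b4,
                              p_one_sided = fit5$p_one_sided,
                              p_two_sided = fit5$p_two_sided,
                              n_snps = fit5$n_snps),
                   file.path(out_dir, "qtl_overlap_gene_adjusted.tsv"))

  manifest <- list(
    version = as.character(utils::packageVersion("aseqtl")),
    seed = config$seed,
    files = c(input_files,
              ase = file.path(out_dir, "ase_results.tsv"),
              eqtl = file.path(out_dir, "eqtl_results.tsv"),
              meta = file.path(out_dir, "meta_results.tsv")),
    counts = list(ase_pairs = nrow(ase), eqtl_pairs = nrow(eqtl),
                  meta_keys = nrow(meta), per_gene_tests = nrow(per_gene)),
    qtl_overlap_verdict = verdict
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
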