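#' Read a phased genotype table
#'
#' Reads phased, biallelic genotypes with parent-of-origin resolved, either
#' from a phased VCF (GT fields written with `|`) or from the package's
#' simple TSV dialect with columns `animal_id`, `snp_id`, `chrom`, `pos`,
#' `paternal_allele`, `maternal_allele`.
#'
#' For VCF input the phased GT field carries two ordered haplotypes but no
#' universal convention for which is which; `haplotype_order` must state it
#' explicitly and is never inferred. Unphased or multiallelic records are
#' dropped; the number dropped is reported via a message and stored in the
#' `n_dropped` attribute.
#'
#' @param path Path to the genotype file.
#' @param format `"tsv"` or `"vcf"`. Defaults from the file extension.
#' @param haplotype_order For VCF input: `"paternal_first"` if the first
#'   haplotype in `GT` is the paternally inherited allele, or
#'   `"maternal_first"`. Required for VCF; ignored for TSV.
#' @return A `data.frame` of class `phased_genotypes` with columns
#'   `animal_id`, `snp_id`, `chrom`, `pos`, `paternal_allele`,
#'   `maternal_allele` (alleles coded 0 = reference, 1 = alternate), and an
#'   attribute `n_dropped`.
#' @export
read_phased_genotypes <- function(path,
                                  format = c("auto", "tsv", "vcf"),
                                  haplotype_order = NULL) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    gt <- .read_vcf_phased(path, haplotype_order)
  } else {
    gt <- utils::read.delim(path, stringsAsFactors = FALSE)
    required <- c("animal_id", "snp_id", "chrom", "pos",
                  "paternal_allele", "maternal_allele")
    if (!all(required %in% names(gt))) {
      stop("phased genotype TSV must have columns: ",
           paste(required, collapse = ", "))
    }
    gt <- gt[required]
    gt$animal_id <- as.character(gt$animal_id)
    gt$snp_id <- as.character(gt$snp_id)
    gt$chrom <- as.character(gt$chrom)
    attr(gt, "n_dropped") <- 0L
  }
  validate_phased_genotypes(gt)
}

.read_vcf_phased <- function(path, haplotype_order) {
  if (is.null(haplotype_order)) {
    stop("haplotype_order must be \"paternal_first\" or \"maternal_first\" ",
         "for VCF input; it cannot be inferred", call. = FALSE)
  }
  haplotype_order <- match.arg(haplotype_order,
                               c("paternal_first", "maternal_first"))
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix),
                     dimnames = list(NULL, names(gt_raw)))
  }
  n_rec <- nrow(gt_raw) * ncol(gt_raw)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])

  long <- data.frame(
    animal_id = rep(colnames(gt_raw), each = nrow(gt_raw)),
    snp_id = rep(snp_id, times = ncol(gt_raw)),
    chrom = rep(fix[, "CHROM"], times = ncol(gt_raw)),
    pos = rep(as.integer(fix[, "POS"]), times = ncol(gt_raw)),
    gt = as.vector(gt_raw),
    biallelic = rep(biallelic, times = ncol(gt_raw)),
    stringsAsFactors = FALSE
  )
  phased <- grepl("^[01]\\|[01]$", long$gt)
  keep <- phased & long$biallelic & !is.na(long$gt)
  n_dropped <- sum(!keep)
  long <- long[keep, , drop = FALSE]
  first <- as.integer(substr(long$gt, 1L, 1L))
  second <- as.integer(substr(long$gt, 3L, 3L))
  if (haplotype_order == "paternal_first") {
    long$paternal_allele <- first
    long$maternal_allele <- second
  } else {
    long$paternal_allele <- second
    long$maternal_allele <- first
  }
  out <- long[c("animal_id", "snp_id", "chrom", "pos",
                "paternal_allele", "maternal_allele")]
  rownames(out) <- NULL
  if (n_dropped > 0) {
    message(n_dropped, " of ", n_rec,
            " VCF genotype records dropped (unphased, missing or multiallelic)")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @keywords internal
validate_phased_genotypes <- function(gt) {
  stopifnot(all(gt$pos >= 1),
            all(gt$paternal_allele %in% c(0L, 1L)),
            all(gt$maternal_allele %in% c(0L, 1L)))
  if (anyDuplicated(paste(gt$animal_id, gt$snp_id))) {
    stop("duplicate (animal, snp) rows in phased genotype table")
  }
  class(gt) <- c("phased_genotypes", "data.frame")
  gt
}

#' Write a phased genotype table as TSV
#' @param gt A `phased_genotypes` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_genotypes <- function(gt, path) {
  utils::write.table(as.data.frame(gt)[c("animal_id", "snp_id", "chrom",
                                         "pos", "paternal_allele",
                                         "maternal_allele")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-animal allele counts at transcript SNPs
#'
#' RNA-seq reads are aligned once to the maternal and once to the paternal
#' customized reference, giving two counts per allele; the two are combined
#' by their arithmetic mean. The file either carries the four per-alignment
#' columns (`maternal_count_mat_ref`, `maternal_count_pat_ref`,
#' `paternal_count_mat_ref`, `paternal_count_pat_ref`) or pre-averaged
#' `maternal_count` / `paternal_count` columns.
#'
#' @param path TSV path with header; must contain `animal_id`, `tsnp_id`
#'   and the count columns described above.
#' @return A `data.frame` of class `allele_counts` with columns `animal_id`,
#'   `tsnp_id`, `maternal_count`, `paternal_count`, `total`.
#' @export
read_allele_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  per_aln <- c("maternal_count_mat_ref", "maternal_count_pat_ref",
               "paternal_count_mat_ref", "paternal_count_pat_ref")
  if (all(per_aln %in% names(x))) {
    maternal <- (x$maternal_count_mat_ref + x$maternal_count_pat_ref) / 2
    paternal <- (x$paternal_count_mat_ref + x$paternal_count_pat_ref) / 2
  } else if (all(c("maternal_count", "paternal_count") %in% names(x))) {
    maternal <- x$maternal_count
    paternal <- x$paternal_count
  } else {
    stop("allele count TSV needs either the four per-alignment count ",
         "columns or maternal_count/paternal_count")
  }
  if (any(maternal < 0) || any(paternal < 0)) {
    stop("negative allele counts")
  }
  allele_counts(x$animal_id, x$tsnp_id, maternal, paternal)
}

#' Construct an allele-count table
#' @param animal_id,tsnp_id Identifiers (recycled as usual).
#' @param maternal_count,paternal_count Averaged counts per parental allele;
#'   may be non-integer (means of two alignments).
#' @return `allele_counts` data.frame; `total` is the Eq.-style weight
#'   \eqn{T =} maternal + paternal.
#' @export
allele_counts <- function(animal_id, tsnp_id, maternal_count, paternal_count) {
  stopifnot(all(maternal_count >= 0), all(paternal_count >= 0))
  out <- data.frame(animal_id = animal_id, tsnp_id = tsnp_id,
                    maternal_count = maternal_count,
                    paternal_count = paternal_count,
                    total = maternal_count + paternal_count,
                    stringsAsFactors = FALSE)
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' Read a gene-by-animal raw count matrix
#'
#' @param path TSV with a `gene_id` column followed by one integer column
#'   per animal.
#' @return Integer matrix, genes in rows (rownames = gene ids), animals in
#'   columns.
#' @export
read_gene_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("gene_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative gene counts")
  m
}

#' Write a gene count matrix as TSV
#' @param counts Gene x animal matrix with rownames.
#' @param path Output path.
#' @export
write_gene_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (GFF3, BED, or annotation TSV)
#'
#' Internal coordinates are 1-based inclusive throughout the package,
#' matching GFF3; BED's 0-based half-open intervals are converted at this
#' boundary (start + 1). GFF3/BED parsing goes through rtracklayer.
#'
#' @param path Annotation file; format from extension (`.gff`/`.gff3`,
#'   `.bed`, else TSV with `gene_id`, `chrom`, `start`, `end`).
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path) || grepl("\\.bed$", path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3/BED requires the rtracklayer package")
    }
    gr <- as.data.frame(rtracklayer::import(path))
    if (grepl("\\.gff3?$", path)) {
      is_gene <- as.character(gr$type) == "gene"
      if (any(is_gene)) gr <- gr[is_gene, , drop = FALSE]
      ids <- if (!is.null(gr$ID)) as.character(gr$ID)
        else as.character(gr$gene_id)
    } else {
      ids <- if (!is.null(gr$name)) as.character(gr$name)
        else paste0("gene", seq_len(nrow(gr)))
    }
    ann <- data.frame(gene_id = ids,
                      chrom = as.character(gr$seqnames),
                      start = gr$start,
                      end = gr$end,
                      stringsAsFactors = FALSE)
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(ann)))
    ann <- ann[c("gene_id", "chrom", "start", "end")]
    ann$gene_id <- as.character(ann$gene_id)
    ann$chrom <- as.character(ann$chrom)
  }
  if (any(ann$end < ann$start)) stop("annotation has end < start")
  ann
}

#' Write gene annotation
#'
#' `format = "bed"` converts back to 0-based half-open starts so that a
#' BED -> internal -> BED round trip reproduces the input; `"gff3"` writes
#' minimal gene features; `"tsv"` writes the internal 1-based table.
#'
#' @param ann Annotation data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param path Output path.
#' @param format `"tsv"`, `"bed"` or `"gff3"` (default from extension).
#' @export
write_annotation <- function(ann, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path)) "bed"
      else if (grepl("\\.gff3?$", path)) "gff3" else "tsv"
  }
  if (format == "bed") {
    bed <- data.frame(ann$chrom, ann$start - 1L, ann$end, ann$gene_id)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else if (format == "gff3") {
    lines <- c("##gff-version 3",
               paste(ann$chrom, "aseqtl", "gene", ann$start, ann$end,
                     ".", "+", ".", paste0("ID=", ann$gene_id), sep = "\t"))
    writeLines(lines, path)
  } else {
    utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a three-column pedigree
#'
#' @param path TSV with header `animal_id`, `sire_id`, `dam_id`; unknown
#'   parents coded `0`, `NA` or empty.
#' @return A `pedigree` data.frame, topologically sorted so parents precede
#'   offspring; errors on a cycle.
#' @export
read_pedigree <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(x)))
  pedigree(x$animal_id, x$sire_id, x$dam_id)
}

#' Construct and validate a pedigree
#'
#' @param animal_id,sire_id,dam_id Character vectors; unknown parents as
#'   `NA`, `""` or `"0"`.
#' @return `pedigree` data.frame in topological order (every parent's row
#'   precedes its offspring's).
#' @export
pedigree <- function(animal_id, sire_id, dam_id) {
  norm <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "" | p == "0"] <- NA_character_
    p
  }
  ped <- data.frame(animal_id = as.character(animal_id),
                    sire_id = norm(sire_id), dam_id = norm(dam_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$animal_id)) stop("duplicate animal ids in pedigree")
  ped <- .toposort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; stops on a cycle (an animal that is its own ancestor).
.toposort_pedigree <- function(ped) {
  ids <- ped$animal_id
  parent_idx <- cbind(match(ped$sire_id, ids), match(ped$dam_id, ids))
  n <- nrow(ped)
  placed <- logical(n)
  order <- integer(0)
  repeat {
    # a parent with no own row (outside the pedigree) counts as unknown
    p1_ok <- is.na(parent_idx[, 1]) |
      placed[ifelse(is.na(parent_idx[, 1]), 1L, parent_idx[, 1])]
    p2_ok <- is.na(parent_idx[, 2]) |
      placed[ifelse(is.na(parent_idx[, 2]), 1L, parent_idx[, 2])]
    ready <- !placed & p1_ok & p2_ok
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop("pedigree contains a cycle (an animal is its own ancestor)")
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pedigree as TSV
#' @param ped A `pedigree`.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire_id[is.na(out$sire_id)] <- "0"
  out$dam_id[is.na(out$dam_id)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS summary table
#'
#' @param path TSV with header `snp_id`, `chrom`, `pos`, `effect`, `se`,
#'   `p_value` and optionally `trait_id`.
#' @return Data.frame sorted by (chrom, pos); errors if any `p_value` is
#'   outside (0, 1] (p = 0 cannot be converted to a z score) or `se <= 0`.
#' @export
read_gwas <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "effect", "se", "p_value")
  stopifnot(all(required %in% names(x)))
  if (any(x$p_value <= 0 | x$p_value > 1)) {
    stop("GWAS p-values must lie in (0, 1]")
  }
  if (any(x$se <= 0)) stop("GWAS standard errors must be positive")
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Write any result table as headered TSV
#' @param x Data.frame.
#' @param path Output path.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
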