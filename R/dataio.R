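#' Read genotypes from VCF or TSV
#'
#' VCF input must carry a per-sample `DS` (dosage) and/or `GP`
#' (genotype-probability triplet) FORMAT field. When only `DS` is present
#' the triplet is reconstructed as the minimal-entropy (degenerate)
#' completion and the table is flagged accordingly. The TSV dialect is the
#' one written by [write_genotypes_tsv()]: columns `variant_id`, `chrom`,
#' `pos`, `ref`, `alt`, `info`, then one `DS:<sample>` column per sample and
#' optionally `GP:<sample>` columns holding comma-joined triplets.
#'
#' @param path file path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by extension).
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  info_str <- vcfR::extract.info(v, element = "INFO")
  variants$info <- if (is.null(info_str)) NA_real_ else
    suppressWarnings(as.numeric(info_str))
  fmt <- colnames(v@gt)[1]
  has_ds <- grepl("(^|:)DS(:|$)", v@gt[, 1])
  has_gp <- grepl("(^|:)GP(:|$)", v@gt[, 1])
  if (!any(has_ds) && !any(has_gp))
    stop("unsupported format: VCF carries neither DS nor GP FORMAT fields")
  samples <- colnames(v@gt)[-1]
  if (any(has_gp)) {
    gp_str <- vcfR::extract.gt(v, element = "GP")
    parts <- strsplit(as.vector(gp_str), ",", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad))
      stop("malformed GP triplet at record ",
           ((bad[1] - 1) %% nrow(gp_str)) + 1)
    num <- suppressWarnings(vapply(parts, as.numeric, numeric(3)))
    dims <- list(variants$variant_id, samples)
    gp <- list(ref = matrix(num[1, ], nrow(variants), dimnames = dims),
               het = matrix(num[2, ], nrow(variants), dimnames = dims),
               alt = matrix(num[3, ], nrow(variants), dimnames = dims))
    dosage <- gp$het + 2 * gp$alt
    genotype_table(variants, dosage, gp)
  } else {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (anyNA(ds)) stop("malformed DS value at record ",
                        which(apply(is.na(ds), 1, any))[1])
    dimnames(ds) <- list(variants$variant_id, samples)
    genotype_table(variants, ds)
  }
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ds_cols <- grep("^DS:", names(df), value = TRUE)
  gp_cols <- grep("^GP:", names(df), value = TRUE)
  if (!length(ds_cols)) stop("unsupported format: no DS:<sample> columns")
  samples <- sub("^DS:", "", ds_cols)
  variants <- df[, c("variant_id", "chrom", "pos", "ref", "alt", "info")]
  dosage <- as.matrix(df[, ds_cols])
  dimnames(dosage) <- list(variants$variant_id, samples)
  gp <- NULL
  if (length(gp_cols)) {
    if (!setequal(sub("^GP:", "", gp_cols), samples))
      stop("GP columns do not match DS columns")
    gp_cols <- paste0("GP:", samples)
    parts <- strsplit(unlist(df[, gp_cols], use.names = FALSE), ",",
                      fixed = TRUE)
    if (any(lengths(parts) != 3)) stop("malformed GP triplet in TSV")
    num <- vapply(parts, as.numeric, numeric(3))
    dims <- dimnames(dosage)
    gp <- list(ref = matrix(num[1, ], nrow(df), dimnames = dims),
               het = matrix(num[2, ], nrow(df), dimnames = dims),
               alt = matrix(num[3, ], nrow(df), dimnames = dims))
  }
  genotype_table(variants, dosage, gp)
}

#' Write genotypes as TSV
#'
#' @param g a [genotype_table()].
#' @param path output path.
#' @param gp write the genotype-probability triplets too.
#' @param digits significant digits used for serialization.
#' @export
write_genotypes_tsv <- function(g, path, gp = TRUE, digits = 15) {
  df <- g$variants[, c("variant_id", "chrom", "pos", "ref", "alt", "info")]
  ds <- as.data.frame(signif(g$dosage, digits))
  names(ds) <- paste0("DS:", g$samples)
  out <- cbind(df, ds)
  if (gp) {
    gpm <- matrix(paste(signif(g$gp$ref, digits), signif(g$gp$het, digits),
                        signif(g$gp$alt, digits), sep = ","),
                  nrow(g$dosage))
    gpd <- as.data.frame(gpm, stringsAsFactors = FALSE)
    names(gpd) <- paste0("GP:", g$samples)
    out <- cbind(out, gpd)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write expression tables
#'
#' TSV dialect: `gene_id`, `chrom`, `tss`, `strand`, then one column per
#' sample. The processing stage travels in a `# stage:` comment line.
#'
#' @param path file path.
#' @return an [expression_table()].
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1)
  stage <- if (grepl("^# stage:", first))
    sub("^# stage:\\s*", "", first) else "raw"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- df[, c("gene_id", "chrom", "tss", "strand")]
  values <- as.matrix(df[, setdiff(names(df), names(genes)), drop = FALSE])
  rownames(values) <- genes$gene_id
  expression_table(genes, values, stage = stage)
}

#' @rdname read_expression_tsv
#' @param e an [expression_table()].
#' @export
write_expression_tsv <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# stage: ", e$stage), con)
  df <- cbind(e$genes[, c("gene_id", "chrom", "tss", "strand")],
              as.data.frame(e$values))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write pedigree tables
#'
#' TSV with columns `sample_id`, `family_id`, `zygosity`.
#' @param path file path.
#' @return a [twin_cohort()].
#' @export
read_pedigree_tsv <- function(path) {
  twin_cohort(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_pedigree_tsv
#' @param cohort a [twin_cohort()].
#' @export
write_pedigree_tsv <- function(cohort, path) {
  utils::write.table(cohort$pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quality-control filters for variants and genes
#'
#' Removes variants with minor-allele frequency below `maf_min` or
#' imputation info below `info_min` (strict inequalities: a variant at
#' exactly the threshold is retained; variants with missing info are
#' retained), and genes whose fraction of zero values exceeds
#' `zero_frac_max`. Idempotent.
#'
#' @param g a [genotype_table()].
#' @param e an [expression_table()] (raw counts/RPKM stage for the
#'   zero-fraction rule).
#' @param maf_min,info_min,zero_frac_max thresholds.
#' @return list with filtered `genotypes`, `expression`, and a `report`
#'   data.frame of removals with reasons.
#' @export
apply_qc_filters <- function(g, e, maf_min = 0.01, info_min = 0.8,
                             zero_frac_max = 0.10) {
  maf_fail <- g$variants$maf < maf_min
  info_fail <- !is.na(g$variants$info) & g$variants$info < info_min
  drop_v <- maf_fail | info_fail
  zero_frac <- rowMeans(e$values == 0)
  drop_g <- zero_frac > zero_frac_max
  report <- rbind(
    data.frame(id = g$variants$variant_id[drop_v],
               type = rep("variant", sum(drop_v)),
               reason = ifelse(maf_fail[drop_v], "maf", "info"),
               stringsAsFactors = FALSE),
    data.frame(id = e$genes$gene_id[drop_g],
               type = rep("gene", sum(drop_g)),
               reason = rep("zero_fraction", sum(drop_g)),
               stringsAsFactors = FALSE))
  if (all(drop_v)) warning("no variants survive QC")
  if (all(drop_g)) warning("no genes survive QC")
  ef <- e
  ef$genes <- e$genes[!drop_g, , drop = FALSE]
  ef$values <- e$values[!drop_g, , drop = FALSE]
  list(genotypes = g[!drop_v], expression = ef, report = report)
}

#' Cis-window and trans-mask variant selection
#'
#' The cis window is the closed interval within `half_width` (default
#' 1 Mbp) of the gene's TSS on the gene's chromosome; trans variants lie
#' strictly farther than `min_distance` (default 5 Mbp) from the TSS or on
#' another chromosome. Coordinates are 1-based inclusive; the two sets
#' never overlap.
#'
#' @param g a [genotype_table()].
#' @param gene one-row gene annotation with `chrom` and `tss`.
#' @param half_width cis half-width in bp.
#' @return character vector of variant ids, ordered by position.
#' @export
cis_window_variants <- function(g, gene, half_width = 1e6) {
  v <- g$variants
  if (!gene$chrom %in% v$chrom) {
    warning("no variants on chromosome ", gene$chrom)
    return(character(0))
  }
  keep <- v$chrom == gene$chrom & abs(v$pos - gene$tss) <= half_width
  ids <- v$variant_id[keep]
  ids[order(v$pos[keep])]
}

#' @rdname cis_window_variants
#' @param min_distance trans distance threshold in bp (strict).
#' @export
trans_mask <- function(g, gene, min_distance = 5e6) {
  v <- g$variants
  keep <- v$chrom != gene$chrom |
    (v$chrom == gene$chrom & abs(v$pos - gene$tss) > min_distance)
  ids <- v$variant_id[keep]
  ids[order(v$chrom[keep], v$pos[keep])]
}
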