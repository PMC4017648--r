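#' Genotype table
#'
#' Container for per-variant genotype dosages and genotype-probability
#' triplets across samples. Dosages are alternate-allele expected counts in
#' [0, 2]; the probability triplet holds P(ref-hom), P(het), P(alt-hom).
#' Minor-allele frequency is computed from dosages (2n denominator), not
#' from hard calls.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt` and optionally `info` (imputation quality in
#'   [0, 1] or `NA`).
#' @param dosage numeric matrix, variants x samples, entries in [0, 2].
#' @param gp optional list of three variants x samples matrices named
#'   `ref`, `het`, `alt`; each triplet must sum to 1 within `1e-6` and be
#'   consistent with the dosage (`dosage == het + 2*alt` within `1e-6`).
#'   When absent, a degenerate triplet is reconstructed from the dosage
#'   (minimal-entropy completion) and flagged.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(variants, dosage, gp = NULL) {
  stopifnot(is.data.frame(variants), is.matrix(dosage))
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols))
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(variants) != nrow(dosage))
    stop("variants and dosage row counts differ")
  if (is.null(colnames(dosage)))
    stop("dosage matrix must carry sample names as column names")
  if (any(dosage < -1e-6 | dosage > 2 + 1e-6))
    stop("dosages must lie in [0, 2]")
  dosage <- pmin(pmax(dosage, 0), 2)
  degenerate <- is.null(gp)
  if (degenerate) {
    gp <- gp_from_dosage(dosage)
  } else {
    stopifnot(all(c("ref", "het", "alt") %in% names(gp)))
    tot <- gp$ref + gp$het + gp$alt
    if (any(abs(tot - 1) > 1e-6))
      stop("genotype-probability triplets must sum to 1")
    implied <- gp$het + 2 * gp$alt
    if (any(abs(implied - dosage) > 1e-4))
      stop("dosage inconsistent with genotype probabilities")
  }
  if (!"info" %in% names(variants)) variants$info <- NA_real_
  f <- rowMeans(dosage) / 2
  variants$maf <- pmin(f, 1 - f)
  structure(
    list(variants = variants, dosage = dosage, gp = gp,
         samples = colnames(dosage), degenerate_gp = degenerate),
    class = "genotype_table")
}

# Minimal-entropy completion: dosage d in [0,1] -> (1-d, d, 0); d in (1,2]
# -> (0, 2-d, d-1). Mass sits on the two adjacent hard genotypes.
gp_from_dosage <- function(dosage) {
  het <- ifelse(dosage <= 1, dosage, 2 - dosage)
  alt <- ifelse(dosage <= 1, 0, dosage - 1)
  ref <- 1 - het - alt
  dn <- dimnames(dosage)
  list(ref = matrix(ref, nrow(dosage), dimnames = dn),
       het = matrix(het, nrow(dosage), dimnames = dn),
       alt = matrix(alt, nrow(dosage), dimnames = dn))
}

#' @exportS3Method print genotype_table
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d variants x %d samples%s\n",
              nrow(x$variants), length(x$samples),
              if (x$degenerate_gp) " (degenerate GP from dosage)" else ""))
  cat(sprintf("  chrom: %s  MAF range: [%.3f, %.3f]\n",
              paste(unique(x$variants$chrom), collapse = ","),
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' @export
`[.genotype_table` <- function(x, i, ...) {
  keep <- seq_len(nrow(x$variants))[i]
  gt <- x
  gt$variants <- x$variants[keep, , drop = FALSE]
  gt$dosage <- x$dosage[keep, , drop = FALSE]
  gt$gp <- lapply(x$gp, function(m) m[keep, , drop = FALSE])
  hap <- attr(x, "haplotypes")
  if (!is.null(hap)) {
    hap$H <- hap$H[keep, , drop = FALSE]
    attr(gt, "haplotypes") <- hap
  }
  gt
}

#' Expression table
#'
#' Gene x sample phenotype matrix with gene annotation (chromosome, TSS,
#' strand) and a processing-stage tag. Stages progress
#' raw -> transformed -> factor-removed -> normalized -> grammar-residual;
#' the preprocessing operations refuse out-of-order input.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @param values numeric matrix, genes x samples, sample names as columns.
#' @param stage processing-stage tag.
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(genes, values,
                             stage = c("raw", "transformed", "factor-removed",
                                       "normalized", "grammar-residual")) {
  stage <- match.arg(stage)
  stopifnot(is.data.frame(genes), is.matrix(values))
  req <- c("gene_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols))
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (nrow(genes) != nrow(values)) stop("genes and values row counts differ")
  if (is.null(colnames(values)))
    stop("values matrix must carry sample names as column names")
  structure(list(genes = genes, values = values,
                 samples = colnames(values), stage = stage),
            class = "expression_table")
}

#' @exportS3Method print expression_table
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples [stage: %s]\n",
              nrow(x$genes), length(x$samples), x$stage))
  invisible(x)
}

#' Twin cohort
#'
#' Sample-to-family map with zygosity. Families have one or two members;
#' MZ and DZ families have exactly two. Zygosity determines the sharing of
#' the family and MZ random intercepts in the twin mixed model.
#'
#' @param pedigree data.frame with columns `sample_id`, `family_id`,
#'   `zygosity` (one of `MZ`, `DZ`, `singleton`).
#' @return an object of class `twin_cohort`.
#' @export
twin_cohort <- function(pedigree) {
  stopifnot(is.data.frame(pedigree))
  req <- c("sample_id", "family_id", "zygosity")
  missing_cols <- setdiff(req, names(pedigree))
  if (length(missing_cols))
    stop("pedigree lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(pedigree$sample_id)) stop("duplicate sample_id")
  if (!all(pedigree$zygosity %in% c("MZ", "DZ", "singleton")))
    stop("zygosity must be MZ, DZ or singleton")
  sizes <- table(pedigree$family_id)
  if (any(sizes > 2)) stop("families may have at most 2 members")
  zyg_by_fam <- tapply(pedigree$zygosity, pedigree$family_id,
                       function(z) length(unique(z)))
  if (any(zyg_by_fam > 1)) stop("zygosity must be constant within family")
  twin_fams <- names(sizes)[sizes == 2]
  z2 <- pedigree$zygosity[match(twin_fams, pedigree$family_id)]
  if (any(!z2 %in% c("MZ", "DZ")))
    stop("two-member families must be MZ or DZ")
  z1 <- pedigree$zygosity[pedigree$family_id %in% names(sizes)[sizes == 1]]
  if (any(z1 != "singleton"))
    stop("one-member families must be singletons")
  structure(list(pedigree = pedigree), class = "twin_cohort")
}

#' @exportS3Method print twin_cohort
print.twin_cohort <- function(x, ...) {
  z <- x$pedigree$zygosity
  fam <- x$pedigree$family_id
  n_mz <- length(unique(fam[z == "MZ"]))
  n_dz <- length(unique(fam[z == "DZ"]))
  n_s <- sum(z == "singleton")
  cat(sprintf("twin_cohort: %d samples (%d MZ pairs, %d DZ pairs, %d singletons)\n",
              nrow(x$pedigree), n_mz, n_dz, n_s))
  invisible(x)
}

# Index the cohort against an ordered sample vector: returns singleton
# positions and pair positions (first/second member) with an MZ flag.
# Every mixed-model computation in the package runs over these 2x2 blocks.
cohort_blocks <- function(cohort, samples) {
  ped <- cohort$pedigree
  idx <- match(ped$sample_id, samples)
  if (anyNA(idx)) {
    ped <- ped[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) < length(samples))
    stop("cohort does not cover all samples")
  fam <- split(seq_along(idx), ped$family_id)
  sizes <- lengths(fam)
  singles <- idx[unlist(fam[sizes == 1], use.names = FALSE)]
  pairs <- fam[sizes == 2]
  if (length(pairs)) {
    p1 <- idx[vapply(pairs, `[`, integer(1), 1L)]
    p2 <- idx[vapply(pairs, `[`, integer(1), 2L)]
    is_mz <- vapply(pairs, function(ii) ped$zygosity[ii[1]] == "MZ",
                    logical(1))
  } else {
    p1 <- p2 <- integer(0); is_mz <- logical(0)
  }
  list(singles = singles, p1 = p1, p2 = p2, is_mz = unname(is_mz),
       family_id = names(pairs))
}
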