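#' Squared-residual distances for the variance test
#'
#' Removes any mean (eQTL) effect of a variant by regressing the phenotype
#' on the posterior probability of being a heterozygote and of being a
#' minor-allele homozygote, then squares the residuals. The squared
#' residual measures each individual's distance from the mean expression of
#' its genotype class (with hard calls the regression saturates the
#' genotype-class means exactly).
#'
#' @param y phenotype vector (relatedness-residual stage).
#' @param gp genotype probabilities for one variant: a list or 3-column
#'   matrix with `ref`, `het`, `alt` probabilities per sample.
#' @return vector of squared residuals.
#' @export
distance_residuals <- function(y, gp) {
  if (is.list(gp)) gp <- cbind(ref = gp$ref, het = gp$het, alt = gp$alt)
  stopifnot(ncol(gp) == 3, nrow(gp) == length(y))
  dosage <- gp[, 2] + 2 * gp[, 3]
  f <- mean(dosage) / 2
  hom_minor <- if (f <= 0.5) gp[, 3] else gp[, 1]
  X <- cbind(1, het = gp[, 2], hom = hom_minor)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::sd) > 1e-10)
  if (!any(keep[-1]))
    stop("variant is monomorphic: genotype design has no variation")
  r <- stats::lm.fit(X[, keep, drop = FALSE], y)$residuals
  r^2
}

#' Spearman test for genotype-dependent variance
#'
#' Tie-corrected Spearman rank correlation between the squared-residual
#' distance and the genotype dosage, with a two-sided p-value from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param d distance vector from [distance_residuals()].
#' @param dosage genotype dosage vector.
#' @return list with `rho`, `p`, and `flag` (`"ok"` or `"constant"`).
#' @export
variance_test <- function(d, dosage) {
  n <- length(d)
  stopifnot(length(dosage) == n)
  if (stats::sd(dosage) == 0) stop("dosage is constant; variant untestable")
  if (stats::sd(d) == 0)
    return(list(rho = 0, p = 1, flag = "constant"))
  rho <- stats::cor(rank(d), rank(dosage))
  p <- spearman_p(rho, n)
  list(rho = rho, p = p, flag = "ok")
}

spearman_p <- function(rho, n) {
  rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

#' Scan one gene's cis window for variance effects
#'
#' Tests every variant in the window with the squared-residual Spearman
#' statistic, flags the peak (minimum p; ties broken by genomic position),
#' and records the permutation null: each of the `n_perm` shared
#' permutations is applied to the distance vector and the per-permutation
#' peak p over the window is kept.
#'
#' @param y phenotype vector.
#' @param window a list with `dosage` (variants x samples matrix), `gp`
#'   (list of ref/het/alt matrices) and `pos` (positions); rows are the
#'   window's variants.
#' @param perms integer matrix (samples x n_perm) of shared permutation
#'   indices.
#' @return data.frame of per-variant results with attribute `perm_peak_p`
#'   (length n_perm) and `skipped` (untestable variant ids).
#' @export
scan_gene <- function(y, window, perms) {
  ids <- rownames(window$dosage)
  nv <- nrow(window$dosage)
  if (nv == 0) stop("empty window")
  n <- length(y)
  n_perm <- ncol(perms)
  rho <- p <- rep(NA_real_, nv)
  perm_p <- matrix(NA_real_, nv, n_perm)
  testable <- logical(nv)
  proj <- window$proj
  Rd <- matrix(NA_real_, n, nv)    # standardized ranks of the distances
  for (v in seq_len(nv)) {
    if (is.null(proj)) {
      gp <- cbind(window$gp$ref[v, ], window$gp$het[v, ],
                  window$gp$alt[v, ])
      d <- tryCatch(distance_residuals(y, gp), error = function(e) NULL)
      if (is.null(d)) next
    } else {
      # precomputed orthonormal basis of [1, P(het), P(hom_minor)]:
      # residual = y - Q (Q'y)
      Q <- proj[[v]]
      if (is.null(Q)) next
      r <- y - Q %*% crossprod(Q, y)
      d <- r * r
    }
    if (stats::sd(window$dosage[v, ]) == 0 || stats::sd(d) == 0) next
    testable[v] <- TRUE
    rd <- rank(d)
    rd <- rd - mean(rd)
    Rd[, v] <- rd / sqrt(sum(rd^2))
  }
  if (!any(testable)) stop("no testable variants in window")
  # standardized dosage ranks (precomputable per run)
  Rg <- window$rank_g_std
  if (is.null(Rg)) {
    Rg <- apply(window$dosage, 1, function(dd) {
      rg <- rank(dd); rg <- rg - mean(rg); rg / sqrt(sum(rg^2))
    })
  }
  ok <- which(testable)
  rho[ok] <- colSums(Rd[, ok, drop = FALSE] * Rg[, ok, drop = FALSE])
  p[ok] <- spearman_p(rho[ok], n)
  # permutations reuse the precomputed ranks: permuting d permutes ranks,
  # and standardization is permutation-invariant
  for (k in seq_len(n_perm)) {
    Pk <- Rd[perms[, k], ok, drop = FALSE]
    perm_p[ok, k] <- spearman_p(colSums(Pk * Rg[, ok, drop = FALSE]), n)
  }
  out <- data.frame(variant_id = ids, pos = window$pos, rho = rho, p = p,
                    stringsAsFactors = FALSE)
  ok <- which(testable)
  peak <- ok[order(p[ok], window$pos[ok])][1]
  out$is_peak <- seq_len(nv) == peak
  out$direction <- sign(out$rho)
  attr(out, "perm_peak_p") <- apply(perm_p[ok, , drop = FALSE], 2, min)
  attr(out, "skipped") <- ids[!testable]
  out
}

#' Permutation false discovery rate for peak p-values
#'
#' Implements the shared-permutation FDR: at threshold t the estimate is
#' the number of permuted peak statistics at or below t divided by the
#' number of permutations, divided by the number of observed peaks at or
#' below t. Estimates are evaluated at each observed peak p-value, made
#' monotone nondecreasing in p, and capped at 1.
#'
#' @param obs_p observed per-gene peak p-values.
#' @param perm_p pooled permuted peak p-values (all genes x permutations).
#' @param n_perm number of permutations the pool came from.
#' @return per-gene FDR vector aligned with `obs_p`.
#' @export
permutation_fdr <- function(obs_p, perm_p, n_perm = 5) {
  stopifnot(n_perm >= 1)
  ord <- order(obs_p)
  sorted <- obs_p[ord]
  n_obs_le <- seq_along(sorted)
  n_perm_le <- findInterval(sorted, sort(perm_p))
  raw <- (n_perm_le / n_perm) / n_obs_le
  mono <- rev(cummin(rev(pmin(raw, 1))))
  fdr <- numeric(length(obs_p))
  fdr[ord] <- mono
  fdr
}

#' Genome-wide variance-eQTL scan
#'
#' Runs [scan_gene()] for every gene against the variants within
#' `half_width` of its TSS, using one set of `n_perm` permutations drawn
#' from `seed` and shared across all gene-variant tests (preserving the
#' linkage-disequilibrium structure of the null), then computes the
#' permutation FDR over per-gene peak p-values.
#'
#' @param e an [expression_table()] at stage `grammar-residual` (twin
#'   cohorts) or `normalized` (unrelated cohorts).
#' @param g a [genotype_table()].
#' @param half_width cis window half-width in bp.
#' @param n_perm number of shared permutations.
#' @param seed integer seed for the permutation indices.
#' @return object of class `veqtl_scan`: list with `peaks` (per-gene
#'   data.frame gene_id, variant_id, pos, rho, p, fdr), `variants`
#'   (per-variant results), `perms`, `skipped_genes`.
#' @export
scan_veqtl <- function(e, g, half_width = 1e6, n_perm = 5, seed = 1) {
  check_stage(e, c("grammar-residual", "normalized"), "scan_veqtl")
  n <- length(e$samples)
  if (!identical(colnames(g$dosage), e$samples))
    stop("sample columns of expression and genotypes differ")
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  # the mean-removal projection per variant is gene-independent: build the
  # orthonormal design bases once for the whole run
  proj_all <- lapply(seq_len(nrow(g$dosage)), function(v) {
    gp <- cbind(g$gp$ref[v, ], g$gp$het[v, ], g$gp$alt[v, ])
    dosage <- gp[, 2] + 2 * gp[, 3]
    f <- mean(dosage) / 2
    hom <- if (f <= 0.5) gp[, 3] else gp[, 1]
    X <- cbind(1, gp[, 2], hom)
    keep <- c(TRUE, stats::sd(gp[, 2]) > 1e-10, stats::sd(hom) > 1e-10)
    if (!any(keep[-1])) return(NULL)
    qr.Q(qr(X[, keep, drop = FALSE]))
  })
  rank_g_all <- apply(g$dosage, 1, function(dd) {
    rg <- rank(dd); rg <- rg - mean(rg)
    s <- sqrt(sum(rg^2))
    if (s > 0) rg / s else rg
  })
  peaks <- NULL; all_res <- list(); perm_pool <- NULL
  skipped <- character(0)
  for (i in seq_len(nrow(e$genes))) {
    gid <- e$genes$gene_id[i]
    ids <- cis_window_variants(g, e$genes[i, ], half_width)
    if (!length(ids)) { skipped <- c(skipped, gid); next }
    vi <- match(ids, g$variants$variant_id)
    window <- list(dosage = g$dosage[vi, , drop = FALSE],
                   gp = lapply(g$gp, function(m) m[vi, , drop = FALSE]),
                   pos = g$variants$pos[vi],
                   proj = proj_all[vi],
                   rank_g_std = rank_g_all[, vi, drop = FALSE])
    res <- tryCatch(scan_gene(e$values[i, ], window, perms),
                    error = function(err) NULL)
    if (is.null(res)) { skipped <- c(skipped, gid); next }
    res$gene_id <- gid
    all_res[[gid]] <- res
    pk <- res[res$is_peak, ]
    peaks <- rbind(peaks, data.frame(
      gene_id = gid, variant_id = pk$variant_id, pos = pk$pos,
      rho = pk$rho, p = pk$p, direction = pk$direction,
      stringsAsFactors = FALSE))
    perm_pool <- c(perm_pool, attr(res, "perm_peak_p"))
  }
  if (is.null(peaks)) stop("no testable genes")
  peaks$fdr <- permutation_fdr(peaks$p, perm_pool, n_perm)
  structure(list(peaks = peaks, variants = all_res, perms = perms,
                 skipped_genes = skipped, n_perm = n_perm),
            class = "veqtl_scan")
}

#' @exportS3Method print veqtl_scan
print.veqtl_scan <- function(x, fdr = 0.05, ...) {
  cat(sprintf("veqtl_scan: %d genes tested, %d peaks at FDR < %.2f\n",
              nrow(x$peaks), sum(x$peaks$fdr < fdr), fdr))
  invisible(x)
}

#' @exportS3Method plot veqtl_scan
plot.veqtl_scan <- function(x, ...) {
  plot(x$peaks$pos, -log10(x$peaks$p), xlab = "peak position (bp)",
       ylab = expression(-log[10](p)), pch = 16,
       col = ifelse(x$peaks$fdr < 0.05, "firebrick", "grey40"), ...)
  invisible(x)
}
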