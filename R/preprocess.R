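# Stage ordering: each operation accepts only the stages listed, so the
# pipeline cannot run out of order (transform -> factor removal -> quantile
# normalization -> relatedness residuals).
check_stage <- function(e, allowed, op) {
  if (!e$stage %in% allowed)
    stop(sprintf("%s expects stage %s but got '%s'", op,
                 paste(sQuote(allowed), collapse = "/"), e$stage))
}

#' Variance-stabilizing transform of expression
#'
#' RNA-seq read counts are approximately Poisson, which couples mean and
#' variance; a square-root transform breaks that link so that mean effects
#' are not mistaken for variance effects. `log` applies `log(1 + x)` (used
#' as a heteroskedasticity robustness check); `none` is the identity.
#'
#' @param e an [expression_table()] at stage `raw`.
#' @param kind one of `sqrt`, `log`, `none`.
#' @return the table at stage `transformed`.
#' @export
transform_expression <- function(e, kind = c("sqrt", "log", "none")) {
  kind <- match.arg(kind)
  check_stage(e, "raw", "transform_expression")
  v <- e$values
  if (kind == "sqrt") {
    if (any(v < 0)) {
      bad <- which(v < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative value under sqrt at gene %s, sample %s",
                   e$genes$gene_id[bad[1]], e$samples[bad[2]]))
    }
    v <- sqrt(v)
  } else if (kind == "log") {
    v <- log1p(v)
  }
  expression_table(e$genes, v, stage = "transformed")
}

#' Remove latent expression factors by principal-component residualization
#'
#' Broad technical and environmental confounders dominate the leading
#' principal components of the expression matrix; each gene is replaced by
#' its residual after projecting out the top `n_factors` sample-space
#' components. Covariates supplied via `protect` are regressed out of the
#' factors before projection, so their expression signal survives factor
#' removal.
#'
#' @param e an [expression_table()] at stage `transformed` (or `raw` when
#'   no transform is wanted).
#' @param n_factors number of components to remove (0 = centering only).
#' @param protect optional numeric matrix (samples x covariates) of
#'   protected covariates.
#' @return the table at stage `factor-removed` (values centered per gene).
#' @export
remove_latent_factors <- function(e, n_factors, protect = NULL) {
  check_stage(e, c("raw", "transformed"), "remove_latent_factors")
  v <- e$values
  n <- ncol(v)
  if (n_factors >= min(dim(v)))
    stop("n_factors must be below min(genes, samples)")
  vc <- v - rowMeans(v)
  if (n_factors > 0) {
    sv <- svd(vc, nu = 0, nv = min(n_factors + 5, min(dim(vc))))
    if (n_factors > sum(sv$d > 1e-10 * sv$d[1]))
      stop("n_factors is above the matrix rank")
    fac <- sv$v[, seq_len(n_factors), drop = FALSE]
    if (!is.null(protect)) {
      protect <- cbind(1, as.matrix(protect))
      fac <- stats::lm.fit(protect, fac)$residuals
      keep <- colSums(fac^2) > 1e-12
      fac <- fac[, keep, drop = FALSE]
    }
    if (ncol(fac) > 0) {
      qf <- qr.Q(qr(fac))
      vc <- vc - (vc %*% qf) %*% t(qf)
    }
  }
  expression_table(e$genes, vc, stage = "factor-removed")
}

#' Quantile normalization to normal scores
#'
#' Per gene, values are replaced by standard-normal quantiles at offsets
#' `(rank - 0.5) / n`, with average ranks for ties. Output is invariant to
#' any monotone transform of the input; per-gene means are ~0.
#'
#' @param e an [expression_table()] at stage `factor-removed` (or earlier,
#'   for direct use), or a bare numeric matrix/vector.
#' @return table at stage `normalized` (or a matrix/vector to match the
#'   input).
#' @export
quantile_normalize <- function(e) {
  if (!inherits(e, "expression_table")) {
    if (is.matrix(e)) return(t(apply(e, 1, normal_scores)))
    return(normal_scores(e))
  }
  check_stage(e, c("raw", "transformed", "factor-removed"),
              "quantile_normalize")
  v <- t(apply(e$values, 1, normal_scores))
  dimnames(v) <- dimnames(e$values)
  expression_table(e$genes, v, stage = "normalized")
}

normal_scores <- function(x) {
  if (anyNA(x)) stop("quantile normalization requires complete data")
  if (stats::sd(x) == 0) {
    warning("constant gene set to zeros")
    return(rep(0, length(x)))
  }
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Relatedness (GRAMMAR) residuals
#'
#' First stage of the two-stage variance scan: per gene, the null twin
#' mixed model (intercept plus family and MZ random intercepts) is fitted
#' by ML and the best linear unbiased predictions of the random effects,
#' together with the intercept, are subtracted. The returned conditional
#' residuals are free of family correlation and are the phenotype used by
#' the variance-eQTL scan. With an all-singleton cohort this reduces to
#' mean centering.
#'
#' @param e an [expression_table()] at stage `normalized`.
#' @param cohort a [twin_cohort()] covering the samples.
#' @return table at stage `grammar-residual`.
#' @export
grammar_residuals <- function(e, cohort) {
  check_stage(e, "normalized", "grammar_residuals")
  blocks <- cohort_blocks(cohort, e$samples)
  no_pairs <- length(blocks$p1) == 0
  X <- matrix(1, ncol(e$values), 1, dimnames = list(NULL, "(Intercept)"))
  v <- e$values
  for (i in seq_len(nrow(v))) {
    y <- v[i, ]
    if (no_pairs) {
      v[i, ] <- y - mean(y)
      next
    }
    fit <- tryCatch(twin_lmm(y, X, blocks),
                    error = function(err) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("mixed model failed for gene ", e$genes$gene_id[i],
              "; falling back to family-mean centering")
      fam <- cohort$pedigree$family_id[match(e$samples,
                                             cohort$pedigree$sample_id)]
      v[i, ] <- y - stats::ave(y, fam)
    } else {
      v[i, ] <- residuals(fit, type = "conditional")
    }
  }
  expression_table(e$genes, v, stage = "grammar-residual")
}
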