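# Build the fixed-effect design for the epistasis models: intercept,
# v-eQTL additive term (or het/hom probabilities for the dominance
# models), prior interaction pairs in additive coding, then the candidate's
# additive term and optionally its interaction with the v-eQTL.
epistasis_design <- function(sv, prior, cand = NULL, cand_id = "K",
                             with_interaction = FALSE, v_cols = NULL) {
  n <- length(sv)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (is.null(v_cols)) {
    X <- cbind(X, v = sv)
  } else {
    X <- cbind(X, v_het = v_cols$het, v_hom = v_cols$hom)
  }
  for (k in seq_along(prior)) {
    sk <- prior[[k]]
    X <- cbind(X, sk, sv * sk)
    colnames(X)[ncol(X) - 1:0] <- paste0(c("b_", "c_"), names(prior)[k])
  }
  if (!is.null(cand)) {
    X <- cbind(X, cand)
    colnames(X)[ncol(X)] <- paste0("b_", cand_id)
    if (with_interaction) {
      X <- cbind(X, sv * cand)
      colnames(X)[ncol(X)] <- paste0("c_", cand_id)
    }
  }
  X
}

#' Forward-stepwise scan for epistasis with a variance-eQTL
#'
#' Iteratively scans candidate variants for a statistical interaction with
#' the v-eQTL dosage, conditioning on all previously selected pairs. At
#' each step every candidate is tested with a 1-df likelihood ratio test of
#' the interaction coefficient (full model with `b_K S_K + c_K S_v S_K`
#' against the null with the additive `b_K S_K` only), both fitted by ML
#' under the twin mixed model. The minimum-p candidate (ties broken by
#' genomic position) is admitted while its p-value is below the Bonferroni
#' threshold; the scan stops otherwise.
#'
#' @param y phenotype vector.
#' @param sv v-eQTL dosage vector.
#' @param candidates matrix (variants x samples) of candidate dosages with
#'   variant ids as row names; must not contain the v-eQTL itself.
#' @param cohort a [twin_cohort()] or precomputed block index.
#' @param alpha_bonf Bonferroni entry threshold. The default is 0.05
#'   Bonferroni-corrected for a genome-scale interaction scan; supply
#'   `0.05 / n_tests` for a scan of known size.
#' @param positions optional positions aligned with candidate rows (for
#'   deterministic tie-breaking); defaults to row order.
#' @param max_steps safety cap on selected interactions.
#' @param samples sample ids aligned with `y`.
#' @return data.frame of class `epistasis_hits` with one row per selected
#'   interaction: `partner_id`, `step`, `c_hat`, `lrt_p`,
#'   `signed_variance_share`; attribute `trace` records each step's min-p,
#'   `skipped` lists collinear candidates.
#' @export
forward_stepwise_epistasis <- function(y, sv, candidates, cohort,
                                       alpha_bonf = 1.98e-8,
                                       positions = NULL, max_steps = 10,
                                       samples = NULL) {
  if (inherits(cohort, "twin_cohort")) {
    if (is.null(samples)) samples <- names(y)
    if (is.null(samples)) samples <- colnames(candidates)
    cohort <- cohort_blocks(cohort, samples)
  }
  ids <- rownames(candidates)
  if (is.null(positions)) positions <- seq_along(ids)
  pool <- seq_along(ids)
  prior <- list()
  hits <- NULL
  trace <- list()
  skipped <- character(0)
  for (step in seq_len(max_steps)) {
    pvals <- rep(NA_real_, length(pool))
    chats <- rep(NA_real_, length(pool))
    fits <- vector("list", length(pool))
    for (j in seq_along(pool)) {
      ck <- candidates[pool[j], ]
      X1 <- epistasis_design(sv, prior, ck, ids[pool[j]], TRUE)
      lrt <- tryCatch(twin_nested_lrt(y, X1, cohort),
                      error = function(e) NULL)
      if (is.null(lrt)) {
        skipped <- c(skipped, ids[pool[j]]); next
      }
      pvals[j] <- lrt$p
      chats[j] <- unname(lrt$full$coefficients[ncol(X1)])
      fits[[j]] <- lrt$full
    }
    if (all(is.na(pvals))) break
    best <- order(pvals, positions[pool])[1]
    trace[[step]] <- list(step = step, min_p = pvals[best],
                          variant = ids[pool[best]])
    if (is.na(pvals[best]) || pvals[best] >= alpha_bonf) break
    sel <- pool[best]
    fit_sel <- fits[[best]]
    share <- interaction_variance_share(fit_sel, ncol(fit_sel$X))
    hits <- rbind(hits, data.frame(
      partner_id = ids[sel], step = step, c_hat = chats[best],
      lrt_p = pvals[best], signed_variance_share = share,
      pos = positions[sel], stringsAsFactors = FALSE))
    prior <- c(prior, stats::setNames(list(candidates[sel, ]), ids[sel]))
    pool <- setdiff(pool, sel)
    if (!length(pool)) break
  }
  if (is.null(hits))
    hits <- data.frame(partner_id = character(0), step = integer(0),
                       c_hat = numeric(0), lrt_p = numeric(0),
                       signed_variance_share = numeric(0),
                       pos = numeric(0), stringsAsFactors = FALSE)
  structure(hits, trace = trace, skipped = unique(skipped),
            class = c("epistasis_hits", "data.frame"))
}

#' Dominance-conditional screening of epistasis hits
#'
#' A non-additive (dominant) effect of the v-eQTL can masquerade as
#' epistasis with a variant in partial linkage disequilibrium. Each hit is
#' therefore retested in the model it was discovered in, with the additive
#' v-eQTL term replaced by separate heterozygote and minor-homozygote
#' probability terms, so any dominance at the v-eQTL is absorbed before
#' the interaction is tested. Hits whose interaction LRT p-value no longer
#' clears the threshold are dropped.
#'
#' @param hits an `epistasis_hits` data.frame from
#'   [forward_stepwise_epistasis()].
#' @param y phenotype vector.
#' @param sv v-eQTL dosage.
#' @param gp_v genotype-probability triplet of the v-eQTL (list or 3-col
#'   matrix). A degenerate triplet without heterozygote information leaves
#'   hits untestable (retained, flagged).
#' @param candidates candidate dosage matrix used in the discovery scan.
#' @param cohort a [twin_cohort()] or block index.
#' @param alpha_bonf threshold used for removal.
#' @param samples sample ids aligned with `y`.
#' @return `hits` with columns `dominance_p`, `passed_dominance`,
#'   `untestable`; rows failing the filter removed.
#' @export
dominance_conditional_filter <- function(hits, y, sv, gp_v, candidates,
                                         cohort, alpha_bonf = 1.98e-8,
                                         samples = NULL) {
  if (!nrow(hits)) {
    hits$dominance_p <- numeric(0)
    hits$passed_dominance <- logical(0)
    hits$untestable <- logical(0)
    return(hits)
  }
  if (inherits(cohort, "twin_cohort")) {
    if (is.null(samples)) samples <- names(y)
    if (is.null(samples)) samples <- colnames(candidates)
    cohort <- cohort_blocks(cohort, samples)
  }
  if (is.list(gp_v)) gp_v <- cbind(gp_v$ref, gp_v$het, gp_v$alt)
  f <- mean(gp_v[, 2] + 2 * gp_v[, 3]) / 2
  hom_minor <- if (f <= 0.5) gp_v[, 3] else gp_v[, 1]
  v_cols <- list(het = gp_v[, 2], hom = hom_minor)
  untestable_gp <- stats::sd(v_cols$het) < 1e-10
  hits <- hits[order(hits$step), , drop = FALSE]
  dom_p <- rep(NA_real_, nrow(hits))
  untest <- rep(untestable_gp, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (untestable_gp) next
    prior_ids <- hits$partner_id[hits$step < hits$step[i]]
    prior <- stats::setNames(
      lapply(prior_ids, function(id) candidates[id, ]), prior_ids)
    ck <- candidates[hits$partner_id[i], ]
    X1 <- epistasis_design(sv, prior, ck, hits$partner_id[i], TRUE,
                           v_cols = v_cols)
    lrt <- tryCatch(twin_nested_lrt(y, X1, cohort),
                    error = function(e) NULL)
    if (is.null(lrt)) { untest[i] <- TRUE; next }
    dom_p[i] <- lrt$p
  }
  hits$dominance_p <- dom_p
  hits$passed_dominance <- untest | (!is.na(dom_p) & dom_p < alpha_bonf)
  hits$untestable <- untest
  hits[hits$passed_dominance, , drop = FALSE]
}

#' Signed variance share of an interaction term
#'
#' Proportion of phenotypic variance attributable to a fitted interaction
#' term, computed marginal-R2 style: the variance of the fitted term over
#' the variance of the full fixed-effect predictor plus all variance
#' components. The sign is the sign of the interaction coefficient with
#' both dosages coded as alternate-allele counts: positive means the joint
#' alternate alleles raise expression beyond the additive prediction,
#' negative that they lower it.
#'
#' @param fit a `twin_lmm` fit.
#' @param term column index or name of the interaction term in the design.
#' @return signed share in [-1, 1].
#' @export
interaction_variance_share <- function(fit, term) {
  stopifnot(inherits(fit, "twin_lmm"))
  if (!fit$converged) stop("refusing variance share on non-converged fit")
  chat <- fit$coefficients[term]
  term_var <- chat^2 * stats::var(fit$X[, term])
  denom <- stats::var(fit$fitted) + fit$var_fam + fit$var_mz + fit$var_res
  if (denom <= 0) stop("zero total variance")
  unname(sign(chat) * term_var / denom)
}
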