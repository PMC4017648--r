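# Merge population levels with < 3 samples into the largest level.
tidy_population <- function(population) {
  if (is.null(population)) return(NULL)
  population <- as.factor(population)
  tab <- table(population)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    big <- names(tab)[which.max(tab)]
    warning("merging small population levels into '", big, "': ",
            paste(small, collapse = ", "))
    levels(population)[levels(population) %in% small] <- big
  }
  droplevels(population)
}

#' Replication test for an interaction in an unrelated cohort
#'
#' Ordinary least squares fit of
#' `y ~ S_v + S_K + S_v:S_K + population indicators`; the interaction is
#' judged by the two-sided t-test on its coefficient. Also returns the
#' signed variance share of the interaction (variance of the fitted
#' interaction term over fitted-predictor variance plus residual variance,
#' signed by the coefficient).
#'
#' @param y phenotype vector (preprocessed, unrelated samples).
#' @param sv,sk v-eQTL and partner dosages.
#' @param population optional factor of population labels; levels with
#'   fewer than 3 samples are merged into the largest level.
#' @return list with `p`, `c_hat`, `signed_share`, `fit`.
#' @export
replicate_interaction <- function(y, sv, sk, population = NULL) {
  population <- tidy_population(population)
  df <- data.frame(y = y, sv = sv, sk = sk)
  form <- y ~ sv + sk + sv:sk
  if (!is.null(population) && nlevels(population) > 1) {
    df$population <- population
    form <- y ~ sv + sk + population + sv:sk
  }
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)$coefficients
  if (!"sv:sk" %in% rownames(sm))
    stop("interaction term is not estimable (collinear design)")
  c_hat <- sm["sv:sk", "Estimate"]
  p <- sm["sv:sk", "Pr(>|t|)"]
  denom <- stats::var(stats::fitted(fit)) + summary(fit)$sigma^2
  share <- sign(c_hat) * c_hat^2 * stats::var(sv * sk) / denom
  list(p = p, c_hat = c_hat, signed_share = unname(share), fit = fit)
}

#' Forward-stepwise additive eQTL scan
#'
#' Standard forward selection for mean effects: repeatedly add the
#' minimum-p variant (t-test on its dosage conditional on the selected set
#' and population indicators) while the minimum p-value is below
#' `p_enter`.
#'
#' @param y phenotype vector.
#' @param G candidate dosage matrix (variants x samples, ids as row
#'   names); should include rare variants when the scan feeds the
#'   haplotype-effect filter.
#' @param p_enter entry threshold.
#' @param population optional population factor.
#' @param max_steps cap on selected eQTL.
#' @return character vector of selected variant ids (possibly empty).
#' @export
eqtl_forward_scan <- function(y, G, p_enter = 1e-5, population = NULL,
                              max_steps = 20) {
  population <- tidy_population(population)
  base <- matrix(1, length(y), 1)
  if (!is.null(population) && nlevels(population) > 1)
    base <- cbind(base, stats::model.matrix(~population)[, -1, drop = FALSE])
  selected <- character(0)
  pool <- rownames(G)
  for (step in seq_len(max_steps)) {
    if (!length(pool)) break
    pv <- vapply(pool, function(id) {
      X <- cbind(base, G[selected, , drop = FALSE] |> t(), G[id, ])
      fit <- stats::lm.fit(X, y)
      if (any(is.na(fit$coefficients))) return(NA_real_)
      rss1 <- sum(fit$residuals^2)
      df1 <- length(y) - ncol(X)
      se2 <- rss1 / df1
      # t-test on the last coefficient via its GLS variance
      XtX_inv <- tryCatch(chol2inv(chol(crossprod(X))),
                          error = function(e) NULL)
      if (is.null(XtX_inv)) return(NA_real_)
      tstat <- fit$coefficients[ncol(X)] / sqrt(se2 * XtX_inv[ncol(X),
                                                              ncol(X)])
      2 * stats::pt(-abs(tstat), df1)
    }, numeric(1))
    if (all(is.na(pv))) break
    best <- which.min(pv)
    if (is.na(pv[best]) || pv[best] >= p_enter) break
    selected <- c(selected, pool[best])
    pool <- pool[-best]
  }
  selected
}

#' Conditional-eQTL screen for haplotype effects
#'
#' An apparent interaction between two variants can be produced by a
#' single (often rare) causal eQTL whose minor allele sits on a particular
#' haplotype background of the pair (high D', low R-squared). For each
#' record, the interaction model is refitted adding each reported eQTL's
#' dosage in turn, and the maximum conditional interaction p-value across
#' eQTL is recorded. A record survives only if that worst-case p-value
#' still meets the FDR cut-off computed across the tested records
#' (Storey q-value below `fdr_cut`). eQTL collinear with the pair are
#' skipped (conservative). With an empty eQTL list the unconditional p is
#' used.
#'
#' @param records list of per-interaction records, each a list with `y`,
#'   `sv`, `sk`, optional `eqtl` (dosage matrix, ids x samples) and
#'   optional `population`.
#' @param fdr_cut q-value threshold.
#' @return data.frame with `max_p`, `q_value`, `survives`,
#'   `n_eqtl_tested`.
#' @export
haplotype_exclusion_filter <- function(records, fdr_cut = 0.05) {
  max_p <- vapply(records, function(rec) {
    pop <- tidy_population(rec$population)
    df <- data.frame(y = rec$y, sv = rec$sv, sk = rec$sk)
    use_pop <- !is.null(pop) && nlevels(pop) > 1
    if (use_pop) df$population <- pop
    eqtl <- rec$eqtl
    if (is.null(eqtl) || nrow(eqtl) == 0) {
      return(replicate_interaction(rec$y, rec$sv, rec$sk,
                                   rec$population)$p)
    }
    ps <- vapply(seq_len(nrow(eqtl)), function(j) {
      df$eqtl <- eqtl[j, ]
      form <- if (use_pop) y ~ sv + sk + eqtl + population + sv:sk else
        y ~ sv + sk + eqtl + sv:sk
      fit <- stats::lm(form, data = df)
      sm <- summary(fit)$coefficients
      if (!"sv:sk" %in% rownames(sm) || anyNA(stats::coef(fit)))
        return(NA_real_)
      sm["sv:sk", "Pr(>|t|)"]
    }, numeric(1))
    if (all(is.na(ps)))
      return(replicate_interaction(rec$y, rec$sv, rec$sk,
                                   rec$population)$p)
    max(ps, na.rm = TRUE)
  }, numeric(1))
  st <- storey_qvalues(max_p)
  data.frame(max_p = max_p, q_value = st$qvalues,
             survives = st$qvalues < fdr_cut,
             n_eqtl_tested = vapply(records, function(r)
               if (is.null(r$eqtl)) 0L else nrow(r$eqtl), integer(1)))
}

#' Storey q-values with a restricted lambda grid
#'
#' Estimates the null proportion pi0 with the Storey smoother — pi0(lambda)
#' = #\{p > lambda\} / (m (1 - lambda)) fitted with a cubic polynomial over
#' a lambda grid restricted to the observed p-value range (preventing
#' overly lenient correction when the p distribution is truncated) and
#' evaluated at the largest admissible lambda — then computes step-up
#' q-values. pi1 = 1 - pi0 estimates the proportion of true alternatives.
#'
#' @param p p-values in (0, 1].
#' @param lambda candidate grid.
#' @return list with `qvalues`, `pi0`, `pi1`, `lambda` (grid used).
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  grid <- lambda[lambda >= min(p) & lambda <= max(p)]
  if (m < 20 || length(grid) < 4) {
    if (m < 20)
      warning("fewer than 20 p-values: pi0 fixed at 1 (BH fallback)")
    pi0 <- 1
    grid <- numeric(0)
  } else {
    pi0_l <- vapply(grid, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::lm(pi0_l ~ stats::poly(grid, 3))
    pi0 <- stats::predict(fit,
                          newdata = data.frame(grid = max(grid)))[[1]]
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- cummin(pi0 * m * p[ord] / rank(p, ties.method = "max")[ord])
  q <- pmin(q, 1)
  list(qvalues = q, pi0 = pi0, pi1 = 1 - pi0, lambda = grid)
}

#' Cross-cohort concordance of interaction effect sizes
#'
#' @param discovery,replication paired vectors of signed variance shares.
#' @return list with `r` (Pearson correlation), `n_same_sign`, `n`,
#'   `sign_test_p` (exact binomial against 0.5).
#' @export
concordance_summary <- function(discovery, replication) {
  stopifnot(length(discovery) == length(replication))
  ok <- is.finite(discovery) & is.finite(replication)
  x <- discovery[ok]; y <- replication[ok]
  if (length(x) < 3) stop("need at least 3 pairs for a correlation")
  same <- sum(sign(x) == sign(y) & sign(x) != 0)
  bt <- stats::binom.test(same, length(x), 0.5)
  list(r = stats::cor(x, y), n_same_sign = same, n = length(x),
       sign_test_p = bt$p.value)
}
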