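#' Discordance-eQTL test in MZ twin pairs
#'
#' MZ twins share their entire genome, so epistasis and haplotype effects
#' cannot create genotype-dependent differences within MZ pairs; a
#' gene-by-environment interaction can. The variant's additive (eQTL) mean
#' effect is first regressed out — the discordance question concerns
#' variability, not level, and without this step a genuine mean or
#' interaction-induced marginal effect leaks into the genotype term. Then
#' per MZ pair the maximum of the two residual expression values is
#' regressed on the minimum, the pair's (shared) genotype, and their
#' product; genotype-dependent discordance shows up as the max-min
#' relationship being conditional on genotype. The default test is the
#' joint F-test of the genotype main effect and the min-by-genotype
#' interaction; either single term can be tested instead.
#'
#' @param y expression vector (named or aligned with `samples`).
#' @param cohort a [twin_cohort()].
#' @param dosage genotype dosage vector aligned with `y`; must be
#'   identical within each MZ pair.
#' @param samples sample ids aligned with `y` (default `names(y)`).
#' @param test which coefficients to test: `joint` (both), `interaction`
#'   (min x genotype), `main` (genotype).
#' @return list of class `deqtl_result`: `p`, `n_pairs`, `group` (mean
#'   absolute within-pair difference and pair count by rounded genotype,
#'   groups with < 3 pairs flagged), `test`, `fit`.
#' @export
deqtl_test <- function(y, cohort, dosage, samples = NULL,
                       test = c("joint", "interaction", "main")) {
  test <- match.arg(test)
  if (is.null(samples)) samples <- names(y)
  blocks <- cohort_blocks(cohort, samples)
  mz <- which(blocks$is_mz)
  if (length(mz) < 3) stop("need at least 3 MZ pairs")
  if (length(mz) < 10)
    warning("fewer than 10 MZ pairs: the discordance test is weak")
  i1 <- blocks$p1[mz]; i2 <- blocks$p2[mz]
  if (any(abs(dosage[i1] - dosage[i2]) > 1e-6))
    stop("dosage differs within an MZ pair: data-integrity error")
  y <- stats::lm.fit(cbind(1, dosage), y)$residuals
  y1 <- y[i1]; y2 <- y[i2]
  mx <- pmax(y1, y2); mn <- pmin(y1, y2)
  g <- dosage[i1]
  full <- stats::lm(mx ~ mn + g + mn:g)
  null <- switch(test,
                 joint = stats::lm(mx ~ mn),
                 interaction = stats::lm(mx ~ mn + g),
                 main = stats::lm(mx ~ mn + mn:g))
  p <- stats::anova(null, full)[2, "Pr(>F)"]
  dif <- abs(y1 - y2)
  grp <- round(g)
  group <- data.frame(genotype = sort(unique(grp)))
  group$mean_abs_diff <- vapply(group$genotype,
                                function(k) mean(dif[grp == k]), numeric(1))
  group$n_pairs <- vapply(group$genotype,
                          function(k) sum(grp == k), integer(1))
  group$small <- group$n_pairs < 3
  structure(list(p = p, n_pairs = length(mz), group = group, test = test,
                 fit = full), class = "deqtl_result")
}

#' @exportS3Method print deqtl_result
print.deqtl_result <- function(x, ...) {
  cat(sprintf("d-eQTL test (%s): p = %.3g over %d MZ pairs\n", x$test,
              x$p, x$n_pairs))
  print(x$group, row.names = FALSE)
  invisible(x)
}

#' GxE fraction among variance-eQTL
#'
#' Summarizes a set of discordance-test p-values (one per v-eQTL) with the
#' Storey pi1 estimate of the proportion of loci whose variance effect has
#' a gene-by-environment component, plus the count significant at the FDR
#' threshold.
#'
#' @param p vector of [deqtl_test()] p-values.
#' @param fdr FDR threshold for the significant count.
#' @return list with `pi1`, `pi0`, `n_significant`, `qvalues`.
#' @export
gxe_fraction <- function(p, fdr = 0.05) {
  st <- storey_qvalues(p)
  list(pi1 = st$pi1, pi0 = st$pi0,
       n_significant = sum(st$qvalues < fdr), qvalues = st$qvalues)
}
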