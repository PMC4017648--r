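#' Build IBD relatedness matrices for the cis/trans variance model
#'
#' Pairwise proportion of alleles shared identically by descent in the cis
#' window (`pi_cis`), in the trans genome (`pi_trans`), and their Hadamard
#' (elementwise) product (`pi_cistrans`), which loads the cis-by-trans
#' epistatic component. MZ pairs share everything (entries 1); DZ entries
#' come from the IBD table; unrelated entries are 0 and diagonals 1. DZ
#' families without an IBD entry are excluded with a warning.
#'
#' @param cohort a [twin_cohort()].
#' @param ibd data.frame `family_id`, `pi_cis`, `pi_trans`.
#' @return list of class `relatedness_matrices` with `pi_cis`, `pi_trans`,
#'   `pi_cistrans` (sample x sample) and `samples`.
#' @export
build_relatedness <- function(cohort, ibd) {
  ped <- cohort$pedigree
  twin_fams <- unique(ped$family_id[ped$zygosity %in% c("MZ", "DZ")])
  dz_fams <- unique(ped$family_id[ped$zygosity == "DZ"])
  missing <- setdiff(dz_fams, ibd$family_id)
  if (length(missing)) {
    warning("excluding DZ families without IBD entries: ",
            paste(missing, collapse = ", "))
    ped <- ped[!ped$family_id %in% missing, , drop = FALSE]
  }
  n <- nrow(ped)
  samples <- ped$sample_id
  pc <- pt <- diag(1, n)
  dimnames(pc) <- dimnames(pt) <- list(samples, samples)
  blocks <- cohort_blocks(twin_cohort(ped), samples)
  for (k in seq_along(blocks$p1)) {
    i <- blocks$p1[k]; j <- blocks$p2[k]
    if (blocks$is_mz[k]) {
      pc[i, j] <- pc[j, i] <- 1
      pt[i, j] <- pt[j, i] <- 1
    } else {
      row <- match(blocks$family_id[k], ibd$family_id)
      pc[i, j] <- pc[j, i] <- ibd$pi_cis[row]
      pt[i, j] <- pt[j, i] <- ibd$pi_trans[row]
    }
  }
  structure(list(pi_cis = pc, pi_trans = pt, pi_cistrans = pc * pt,
                 samples = samples),
            class = "relatedness_matrices")
}

# Shared ML machinery for linear covariance models on 2x2 twin blocks:
# Omega = sigma_e^2 (I + sum_k r_k P_k) with P_k diag 1 and the given
# off-diagonal loadings per pair. Intercept profiled by GLS, scale
# analytically; optimizer works over log ratios with restarts.
vc_ml <- function(y, singles, p1, p2, offw, restarts = 3,
                  reltol = 1e-10) {
  n <- length(y)
  ncomp <- ncol(offw)
  X <- matrix(1, n, 1)
  grp <- apply(offw, 1, paste, collapse = "/")
  ss <- block_suffstats(y, X, singles, p1, p2, grp)
  # one off-diagonal loading row per pair group
  grp_w <- offw[match(names(ss$pair), grp), , drop = FALSE]
  profile_ll <- function(r) {
    out <- suffstat_profile_ll(ss, 1 + sum(r), drop(grp_w %*% r), n)
    if (is.null(out)) return(NULL)
    list(ll = out$ll, mu = out$beta[1], sigma2 = out$sigma2)
  }
  negll <- function(u) {
    out <- profile_ll(exp(u))
    if (is.null(out)) 1e10 else -out$ll
  }
  starts <- list(rep(0.5, ncomp), rep(0.05, ncomp),
                 rep(1.5, ncomp))[seq_len(max(restarts, 1))]
  best <- Inf; best_u <- NULL; conv <- FALSE
  for (st in starts) {
    op <- tryCatch(stats::optim(log(st), negll, method = "Nelder-Mead",
                                control = list(reltol = reltol,
                                               maxit = 2000)),
                   error = function(e) NULL)
    if (is.null(op)) next
    if (op$value < best - 1e-12) {
      best <- op$value; best_u <- op$par; conv <- op$convergence == 0
    }
  }
  if (is.null(best_u)) stop("variance-components optimizer failed")
  r <- exp(best_u)
  out <- profile_ll(r)
  list(ratios = r, sigma_e2 = out$sigma2, mu = out$mu, loglik = out$ll,
       converged = conv)
}

# Extract 2x2 pair structure and per-pair loadings from relatedness
# matrices (pairs = any nonzero off-diagonal entry).
relatedness_pairs <- function(R) {
  any_off <- (R$pi_cis + R$pi_trans) * upper.tri(R$pi_cis)
  idx <- which(any_off > 0, arr.ind = TRUE)
  n <- nrow(R$pi_cis)
  list(p1 = idx[, 1], p2 = idx[, 2],
       singles = setdiff(seq_len(n), c(idx[, 1], idx[, 2])),
       pc = R$pi_cis[idx], pt = R$pi_trans[idx],
       pct = R$pi_cistrans[idx])
}

#' Fit the cis/trans/cis-by-trans variance-components model
#'
#' Maximum-likelihood fit of the trait covariance
#' \deqn{\Omega = \Pi_{cis}\sigma^2_{cis} + \Pi_{trans}\sigma^2_{trans} +
#' \Pi_{cis-trans}\sigma^2_{cis-trans} + I\sigma^2_e} where the Pi
#' matrices come from [build_relatedness()] and the cis-by-trans loading
#' is their Hadamard product. Components are nonnegative (log-scale
#' optimization with the environmental scale profiled analytically). The
#' headline quantity is the cis-by-trans share
#' \eqn{\sigma^2_{cis-trans} / (\sigma^2_{cis} + \sigma^2_{trans} +
#' \sigma^2_{cis-trans} + \sigma^2_e)}.
#'
#' @param y phenotype vector named by sample or aligned with
#'   `R$samples`.
#' @param R a `relatedness_matrices` object.
#' @param restarts optimizer restarts (fixed starting points).
#' @return object of class `vc_fit` with `var_cis`, `var_trans`,
#'   `var_cistrans`, `var_env`, `share_cistrans`, `loglik`, `converged`.
#' @export
fit_vc <- function(y, R, restarts = 3) {
  if (!is.null(names(y))) y <- y[R$samples]
  stopifnot(length(y) == length(R$samples))
  pr <- relatedness_pairs(R)
  if (length(pr$p1) < 100)
    warning("fewer than 100 informative twin pairs: variance components ",
            "will be imprecise")
  offw <- cbind(cis = pr$pc, trans = pr$pt, cistrans = pr$pct)
  ml <- vc_ml(y, pr$singles, pr$p1, pr$p2, offw, restarts)
  comps <- ml$ratios * ml$sigma_e2
  total <- sum(comps) + ml$sigma_e2
  structure(list(var_cis = comps[1], var_trans = comps[2],
                 var_cistrans = comps[3], var_env = ml$sigma_e2,
                 share_cistrans = unname(comps[3] / total),
                 shares = c(cis = unname(comps[1] / total),
                            trans = unname(comps[2] / total),
                            cistrans = unname(comps[3] / total),
                            env = ml$sigma_e2 / total),
                 mu = ml$mu, loglik = ml$loglik,
                 converged = ml$converged, n_obs = length(y)),
            class = "vc_fit")
}

#' @exportS3Method print vc_fit
print.vc_fit <- function(x, ...) {
  cat("cis/trans variance-components fit (ML)\n")
  cat(sprintf("  cis %.4g  trans %.4g  cis-x-trans %.4g  env %.4g\n",
              x$var_cis, x$var_trans, x$var_cistrans, x$var_env))
  cat(sprintf("  cis-x-trans share: %.3f  logLik: %.3f  converged: %s\n",
              x$share_cistrans, x$loglik, x$converged))
  invisible(x)
}

#' @export
logLik.vc_fit <- function(object, ...) {
  structure(object$loglik, df = 5, nobs = object$n_obs, class = "logLik")
}

#' Compare the cis-by-trans model against a common-environment model
#'
#' The alternative explanation for within-pair covariance beyond additive
#' cis and trans sharing is a shared (common) environment: \deqn{\Omega =
#' \Pi_{cis}\sigma^2_{cis} + \Pi_{trans}\sigma^2_{trans} + C\sigma^2_c +
#' I\sigma^2_e} with `C` the within-twin-pair indicator (both zygosities).
#' Both models are fitted by the same ML machinery and compared by
#' log-likelihood; the models are non-nested so no p-value is attached.
#' A positive difference favours the cis-by-trans (epistasis) model.
#'
#' @param y phenotype vector.
#' @param R a `relatedness_matrices` object.
#' @param cohort the [twin_cohort()] (defines the pair indicator `C`).
#' @param restarts optimizer restarts.
#' @return list with `cistrans` (a `vc_fit`), `common_env` (list of
#'   components and loglik), `delta_loglik`.
#' @export
compare_common_environment <- function(y, R, cohort, restarts = 3) {
  fit_ct <- fit_vc(y, R, restarts)
  if (!is.null(names(y))) y <- y[R$samples]
  blocks <- cohort_blocks(cohort, R$samples)
  pc <- pt <- numeric(length(blocks$p1))
  for (k in seq_along(blocks$p1)) {
    pc[k] <- R$pi_cis[blocks$p1[k], blocks$p2[k]]
    pt[k] <- R$pi_trans[blocks$p1[k], blocks$p2[k]]
  }
  offw <- cbind(cis = pc, trans = pt, common = rep(1, length(pc)))
  ml <- suppressWarnings(
    vc_ml(y, blocks$singles, blocks$p1, blocks$p2, offw, restarts))
  comps <- ml$ratios * ml$sigma_e2
  common_env <- list(var_cis = comps[1], var_trans = comps[2],
                     var_common = comps[3], var_env = ml$sigma_e2,
                     loglik = ml$loglik, converged = ml$converged)
  list(cistrans = fit_ct, common_env = common_env,
       delta_loglik = fit_ct$loglik - common_env$loglik)
}
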