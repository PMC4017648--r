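#' Fit the twin linear mixed model by maximum likelihood
#'
#' Fits \deqn{y = X\beta + \beta_{fam} + \gamma_{mz} + \epsilon} where the
#' family intercept \eqn{\beta_{fam} \sim N(0, \sigma^2_{FAM})} is shared by
#' both members of a twin pair (MZ or DZ), the MZ intercept
#' \eqn{\gamma_{mz} \sim N(0, \sigma^2_{MZ})} is shared only within MZ
#' pairs, and \eqn{\epsilon \sim N(0, \sigma^2)} is individual. The implied
#' marginal covariance has diagonal
#' \eqn{\sigma^2_{FAM}+\sigma^2_{MZ}+\sigma^2}, within-DZ-pair covariance
#' \eqn{\sigma^2_{FAM}}, within-MZ-pair covariance
#' \eqn{\sigma^2_{FAM}+\sigma^2_{MZ}}, and zero between families.
#'
#' Fixed effects are profiled out by generalized least squares and the
#' residual scale is profiled analytically, so the optimizer works over the
#' two log variance ratios only. The likelihood is full ML (not REML);
#' variance components may sit on the nonnegativity boundary. Components
#' are floored at `1e-12` of the phenotype variance, and the optimizer is
#' restarted from three fixed starting points.
#'
#' When the cohort contains no MZ pairs the MZ component is not separately
#' identifiable and is pinned at the floor; likewise with no DZ pairs the
#' family component is pinned (shared pair variance is then attributed to
#' the MZ component). With no pairs at all the fit collapses to ordinary
#' least squares.
#'
#' @param y numeric phenotype vector, aligned with `X` rows and with the
#'   cohort's samples.
#' @param X fixed-effect design matrix (including the intercept column);
#'   must have full column rank.
#' @param cohort a [twin_cohort()] covering the samples, or a precomputed
#'   block index from the internal `cohort_blocks()`.
#' @param samples sample ids aligned with `y`; defaults to `names(y)` or,
#'   failing that, the cohort's pedigree order.
#' @param restarts number of fixed starting points (1 to 3).
#' @param reltol optimizer relative tolerance.
#' @return an object of class `twin_lmm` with components `coefficients`,
#'   `var_fam`, `var_mz`, `var_res`, `loglik`, `converged`, `n_obs`.
#' @export
twin_lmm <- function(y, X, cohort, samples = NULL, restarts = 3,
                     reltol = 1e-10) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  blocks <- if (inherits(cohort, "twin_cohort")) {
    if (is.null(samples)) samples <- names(y)
    if (is.null(samples)) samples <- cohort$pedigree$sample_id
    cohort_blocks(cohort, samples)
  } else cohort
  fit <- twin_lmm_engine(y, X, blocks, restarts = restarts, reltol = reltol)
  fit$call <- match.call()
  fit
}

# Per-group sufficient statistics for the 2x2 block likelihood. Pairs are
# grouped by their off-diagonal loading pattern (for the twin model: DZ vs
# MZ), so every likelihood evaluation is O(p^2) scalar algebra on these
# precomputed pieces rather than O(n).
block_suffstats <- function(y, X, singles, p1, p2, group) {
  groups <- split(seq_along(p1), group)
  Xs <- X[singles, , drop = FALSE]; ys <- y[singles]
  out <- list(
    Cs = crossprod(Xs), Xsys = drop(crossprod(Xs, ys)),
    yys = sum(ys^2), n_s = length(singles),
    pair = lapply(groups, function(ii) {
      A <- X[p1[ii], , drop = FALSE]; B <- X[p2[ii], , drop = FALSE]
      y1 <- y[p1[ii]]; y2 <- y[p2[ii]]
      CAB <- crossprod(A, B)
      list(CAA = crossprod(A) + crossprod(B), CAB = CAB + t(CAB),
           Ay1By2 = drop(crossprod(A, y1) + crossprod(B, y2)),
           Ay2By1 = drop(crossprod(A, y2) + crossprod(B, y1)),
           yy = sum(y1^2) + sum(y2^2), y12 = sum(y1 * y2),
           n = length(ii))
    }))
  out
}

# Profiled log-likelihood at off-diagonal loadings o (one per pair group)
# and common diagonal wd; fixed effects by GLS, scale analytic.
suffstat_profile_ll <- function(ss, wd, o, n) {
  XtWX <- ss$Cs / wd
  XtWy <- ss$Xsys / wd
  ytWy <- ss$yys / wd
  logdet <- ss$n_s * log(wd)
  for (g in seq_along(ss$pair)) {
    pg <- ss$pair[[g]]
    det2 <- wd^2 - o[g]^2
    if (det2 <= 0) return(NULL)
    wa <- wd / det2; wb <- -o[g] / det2
    XtWX <- XtWX + wa * pg$CAA + wb * pg$CAB
    XtWy <- XtWy + wa * pg$Ay1By2 + wb * pg$Ay2By1
    ytWy <- ytWy + wa * pg$yy + 2 * wb * pg$y12
    logdet <- logdet + pg$n * log(det2)
  }
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  ssr <- max(ytWy - sum(beta * XtWy), 1e-300)
  sigma2 <- ssr / n
  ll <- -0.5 * (n * log(2 * pi) + n + n * log(sigma2) + logdet)
  list(ll = ll, beta = drop(beta), sigma2 = sigma2, XtWX = XtWX)
}

# Restrict precomputed sufficient statistics to a subset of design columns
# (used to fit nested models from one set of crossproducts).
subset_suffstats <- function(ss, idx) {
  ss$Cs <- ss$Cs[idx, idx, drop = FALSE]
  ss$Xsys <- ss$Xsys[idx]
  ss$pair <- lapply(ss$pair, function(pg) {
    pg$CAA <- pg$CAA[idx, idx, drop = FALSE]
    pg$CAB <- pg$CAB[idx, idx, drop = FALSE]
    pg$Ay1By2 <- pg$Ay1By2[idx]
    pg$Ay2By1 <- pg$Ay2By1[idx]
    pg
  })
  ss
}

# Profiled ML over the two variance ratios. W = V / sigma^2 with diag
# 1 + af + am, DZ off-diagonal af, MZ off-diagonal af + am.
twin_lmm_engine <- function(y, X, blocks, restarts = 3, reltol = 1e-10,
                            ss = NULL) {
  n <- length(y)
  p <- ncol(X)
  is_mz <- blocks$is_mz
  has_mz <- any(is_mz); has_dz <- any(!is_mz)
  floor_ratio <- 1e-12
  if (is.null(ss)) {
    grp <- ifelse(is_mz, "mz", "dz")
    ss <- block_suffstats(y, X, blocks$singles, blocks$p1, blocks$p2, grp)
  }
  grp_mz <- as.numeric(names(ss$pair) == "mz")
  profile_ll <- function(af, am)
    suffstat_profile_ll(ss, 1 + af + am, af + am * grp_mz, n)

  free <- c(fam = has_dz || has_mz, mz = has_mz)
  # With MZ pairs but no DZ pairs only the sum of the two shared components
  # is identified: pin the family ratio and let the MZ ratio carry it.
  if (has_mz && !has_dz) free["fam"] <- FALSE
  negll <- function(u) {
    af <- if (free["fam"]) exp(u[1]) else floor_ratio
    am <- if (free["mz"]) exp(u[if (free["fam"]) 2 else 1]) else floor_ratio
    out <- profile_ll(af, am)
    if (is.null(out)) return(1e10)
    -out$ll
  }
  n_free <- sum(free)
  starts <- list(c(0.5, 0.5), c(0.1, 0.01), c(2, 1))[seq_len(max(restarts, 1))]
  best <- NULL; best_u <- NULL; conv <- FALSE
  if (n_free == 0) {
    best_u <- numeric(0); conv <- TRUE
  } else {
    vals <- numeric(0)
    for (st in starts) {
      u0 <- log(st[seq_len(n_free)])
      op <- tryCatch(
        if (n_free == 1)
          stats::optim(u0, negll, method = "Brent", lower = -30,
                       upper = 15)
        else
          stats::optim(u0, negll, method = "Nelder-Mead",
                       control = list(reltol = reltol, maxit = 500)),
        error = function(e) NULL)
      if (is.null(op)) next
      vals <- c(vals, op$value)
      if (is.null(best) || op$value < best - 1e-12) {
        best <- op$value; best_u <- op$par
        conv <- op$convergence == 0
      }
      # remaining restarts guard against local maxima; once two starts
      # agree on the optimum there is nothing left to find
      if (length(vals) >= 2 && diff(range(sort(vals)[1:2])) < 1e-7) break
    }
    if (is.null(best_u)) stop("twin_lmm optimizer failed from all starts")
  }
  af <- if (free["fam"]) exp(best_u[1]) else floor_ratio
  am <- if (free["mz"]) exp(best_u[if (free["fam"]) 2 else 1]) else floor_ratio
  out <- profile_ll(af, am)
  beta <- out$beta
  names(beta) <- colnames(X)
  vcov_beta <- tryCatch(solve(out$XtWX) * out$sigma2,
                        error = function(e) matrix(NA, p, p))
  structure(list(
    coefficients = beta,
    var_fam = af * out$sigma2, var_mz = am * out$sigma2,
    var_res = out$sigma2,
    loglik = out$ll, converged = conv, n_obs = n,
    vcov = vcov_beta, X = X, y = y, blocks = blocks,
    fitted = drop(X %*% beta), ratio_fam = af, ratio_mz = am),
    class = "twin_lmm")
}

#' @exportS3Method print twin_lmm
print.twin_lmm <- function(x, digits = 4, ...) {
  cat("Twin linear mixed model (ML)\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Variance components: fam=%.*g mz=%.*g residual=%.*g\n",
              digits, x$var_fam, digits, x$var_mz, digits, x$var_res))
  cat(sprintf("logLik: %.*f  n: %d  converged: %s\n", digits, x$loglik,
              x$n_obs, x$converged))
  invisible(x)
}

#' @export
summary.twin_lmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, var_fam = object$var_fam,
              var_mz = object$var_mz, var_res = object$var_res,
              loglik = object$loglik, n_obs = object$n_obs,
              converged = object$converged)
  class(out) <- "summary.twin_lmm"
  out
}

#' @exportS3Method print summary.twin_lmm
print.summary.twin_lmm <- function(x, ...) {
  cat("Twin linear mixed model (ML)\n\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nVariance components:\n  family %.4g  MZ %.4g  residual %.4g\n",
              x$var_fam, x$var_mz, x$var_res))
  cat(sprintf("logLik %.4f (n = %d)\n", x$loglik, x$n_obs))
  invisible(x)
}

#' @export
coef.twin_lmm <- function(object, ...) object$coefficients

#' @export
logLik.twin_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 3,
            nobs = object$n_obs, class = "logLik")
}

#' @export
fitted.twin_lmm <- function(object, ...) object$fitted

#' Residuals of a twin mixed model
#'
#' `"response"` residuals are marginal (`y - X beta`); `"conditional"`
#' residuals additionally subtract the best linear unbiased predictions of
#' the family and MZ random intercepts, i.e.
#' \eqn{\hat\sigma^2 V^{-1}(y - X\hat\beta)}.
#'
#' @param object a `twin_lmm` fit.
#' @param type residual type.
#' @param ... unused.
#' @export
residuals.twin_lmm <- function(object, type = c("response", "conditional"),
                               ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "response") return(r)
  af <- object$ratio_fam; am <- object$ratio_mz
  b <- object$blocks
  out <- numeric(length(r))
  wd <- 1 + af + am
  out[b$singles] <- r[b$singles] / wd
  if (length(b$p1)) {
    o <- af + am * as.numeric(b$is_mz)
    det2 <- wd^2 - o^2
    r1 <- r[b$p1]; r2 <- r[b$p2]
    out[b$p1] <- (wd * r1 - o * r2) / det2
    out[b$p2] <- (wd * r2 - o * r1) / det2
  }
  out
}

#' @export
predict.twin_lmm <- function(object, newX = NULL, ...) {
  if (is.null(newX)) return(object$fitted)
  drop(as.matrix(newX) %*% object$coefficients)
}

#' @export
simulate.twin_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  b <- object$blocks
  n <- object$n_obs
  out <- replicate(nsim, {
    y <- object$fitted + stats::rnorm(n, 0, sqrt(object$var_res))
    if (length(b$p1)) {
      fam_eff <- stats::rnorm(length(b$p1), 0, sqrt(object$var_fam))
      mz_eff <- stats::rnorm(length(b$p1), 0, sqrt(object$var_mz)) *
        as.numeric(b$is_mz)
      y[b$p1] <- y[b$p1] + fam_eff + mz_eff
      y[b$p2] <- y[b$p2] + fam_eff + mz_eff
    }
    if (length(b$singles))
      y[b$singles] <- y[b$singles] +
        stats::rnorm(length(b$singles), 0, sqrt(object$var_fam)) +
        stats::rnorm(length(b$singles), 0, sqrt(object$var_mz))
    y
  })
  as.data.frame(out)
}

# Fit the full model and the model without its last design column from a
# single set of sufficient statistics; 1-df chi-square LRT on that column.
twin_nested_lrt <- function(y, X_full, blocks, restarts = 3) {
  qrX <- qr(X_full)
  if (qrX$rank < ncol(X_full))
    stop("design is rank deficient")
  grp <- ifelse(blocks$is_mz, "mz", "dz")
  ss <- block_suffstats(y, X_full, blocks$singles, blocks$p1, blocks$p2,
                        grp)
  f1 <- twin_lmm_engine(y, X_full, blocks, restarts, ss = ss)
  p <- ncol(X_full)
  f0 <- twin_lmm_engine(y, X_full[, -p, drop = FALSE], blocks, restarts,
                        ss = subset_suffstats(ss, seq_len(p - 1)))
  stat <- max(0, 2 * (f1$loglik - f0$loglik))
  list(p = stats::pchisq(stat, 1, lower.tail = FALSE), stat = stat,
       full = f1, null = f0)
}

#' Likelihood ratio test of nested twin mixed models
#'
#' Compares two ML fits whose fixed-effect designs are nested; the
#' statistic `2 * (loglik_full - loglik_null)` (clamped at zero) is
#' referred to a chi-square with degrees of freedom equal to the difference
#' in fixed-effect count.
#'
#' @param full,null `twin_lmm` fits; `null` must be nested in `full`.
#' @return list with `stat`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "twin_lmm"), inherits(null, "twin_lmm"))
  if (!full$converged || !null$converged)
    stop("refusing LRT on non-converged fit")
  df <- ncol(full$X) - ncol(null$X)
  if (df < 1) stop("designs are not nested (full has no extra columns)")
  # nestedness: null design columns must lie in the full design's span
  proj <- stats::lm.fit(full$X, null$X)
  if (max(abs(proj$residuals)) > 1e-6 * max(1, max(abs(null$X))))
    stop("designs are not nested")
  stat <- max(0, 2 * (full$loglik - null$loglik))
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
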