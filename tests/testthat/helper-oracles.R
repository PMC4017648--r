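# Dense multivariate-normal oracles, independent of the package's
# block-structured engines: covariance matrices are materialized in full
# and the likelihood maximized directly over the raw variance components.

dense_twin_V <- function(ped, s2f, s2m, s2) {
  n <- nrow(ped)
  V <- diag(s2f + s2m + s2, n)
  for (f in unique(ped$family_id)) {
    idx <- which(ped$family_id == f)
    if (length(idx) == 2) {
      cov <- s2f + if (ped$zygosity[idx[1]] == "MZ") s2m else 0
      V[idx[1], idx[2]] <- V[idx[2], idx[1]] <- cov
    }
  }
  V
}

dense_gls_loglik <- function(y, X, V) {
  n <- length(y)
  ch <- chol(V)
  logdet <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  ll <- -0.5 * (n * log(2 * pi) + logdet + drop(crossprod(r, Vi %*% r)))
  list(ll = ll, beta = drop(beta))
}

dense_twin_ml <- function(y, X, ped) {
  vy <- stats::var(y)
  obj <- function(u) {
    V <- dense_twin_V(ped, exp(u[1]), exp(u[2]), exp(u[3]))
    tryCatch(-dense_gls_loglik(y, X, V)$ll, error = function(e) 1e10)
  }
  best <- NULL
  starts <- list(c(0.3, 0.3, 0.4), c(0.05, 0.05, 0.9), c(0.8, 0.1, 0.1),
                 c(1e-6, 1e-6, 1))
  for (st in starts) {
    op <- stats::optim(log(st * vy), obj,
                       control = list(maxit = 5000, reltol = 1e-13))
    op <- stats::optim(op$par, obj,
                       control = list(maxit = 5000, reltol = 1e-13))
    if (is.null(best) || op$value < best$value) best <- op
  }
  comps <- exp(best$par)
  V <- dense_twin_V(ped, comps[1], comps[2], comps[3])
  out <- dense_gls_loglik(y, X, V)
  list(loglik = out$ll, beta = out$beta, comps = comps)
}

dense_vc_loglik <- function(y, R, comps) {
  n <- length(y)
  V <- comps[1] * R$pi_cis + comps[2] * R$pi_trans +
    comps[3] * R$pi_cistrans + diag(comps[4], n)
  dense_gls_loglik(y, matrix(1, n, 1), V)$ll
}

# Small random twin cohort + simulated phenotype for oracle checks.
random_twin_instance <- function(seed, n_mz = 4, n_dz = 5, n_single = 4,
                                 p_extra = 1) {
  sim <- simulate_cohort(n_mz, n_dz, n_single, seed = seed)
  ped <- sim$cohort$pedigree
  n <- nrow(ped)
  set.seed(seed + 1000)
  X <- cbind(`(Intercept)` = 1,
             matrix(stats::rnorm(n * p_extra), n,
                    dimnames = list(NULL, paste0("x", seq_len(p_extra)))))
  beta <- stats::rnorm(ncol(X))
  blocks <- vamap:::cohort_blocks(sim$cohort, ped$sample_id)
  s2f <- stats::runif(1, 0, 0.8)
  s2m <- stats::runif(1, 0, 0.8)
  y <- drop(X %*% beta) + stats::rnorm(n, 0, 1)
  u <- stats::rnorm(length(blocks$p1), 0, sqrt(s2f))
  y[blocks$p1] <- y[blocks$p1] + u
  y[blocks$p2] <- y[blocks$p2] + u
  v <- stats::rnorm(length(blocks$p1), 0, sqrt(s2m)) *
    as.numeric(blocks$is_mz)
  y[blocks$p1] <- y[blocks$p1] + v
  y[blocks$p2] <- y[blocks$p2] + v
  y[blocks$singles] <- y[blocks$singles] +
    stats::rnorm(length(blocks$singles), 0, sqrt(s2f + s2m))
  names(y) <- ped$sample_id
  list(y = y, X = X, cohort = sim$cohort, ped = ped, ibd = sim$ibd)
}

# Write a minimal VCF with DS and/or GP FORMAT fields.
write_test_vcf <- function(path, with_gp = TRUE, with_ds = TRUE) {
  samples <- c("S1", "S2", "S3")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gp <- list(c("0.1,0.8,0.1", "0.7,0.3,0", "0,0.2,0.8"),
             c("1,0,0", "0.5,0.5,0", "0.25,0.5,0.25"))
  ds <- list(c("1", "0.3", "1.8"), c("0", "0.5", "1"))
  fmt <- paste(c(if (with_ds) "DS", if (with_gp) "GP"), collapse = ":")
  rows <- vapply(1:2, function(i) {
    cells <- vapply(1:3, function(j) {
      paste(c(if (with_ds) ds[[i]][j], if (with_gp) gp[[i]][j]),
            collapse = ":")
    }, character(1))
    paste(c("1", c("1000", "2000")[i], paste0("rs", i), "A", "G", ".",
            "PASS", "INFO=0.95", fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}
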