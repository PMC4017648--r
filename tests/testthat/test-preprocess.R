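make_expr <- function(vals, stage = "raw") {
  if (is.null(dim(vals))) vals <- matrix(vals, 1)
  colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  rownames(vals) <- paste0("g", seq_len(nrow(vals)))
  expression_table(data.frame(gene_id = rownames(vals), chrom = "1",
                              tss = seq_len(nrow(vals)) * 1000L,
                              strand = "+"), vals, stage = stage)
}

test_that("square-root transform stabilizes Poisson variance", {
  e <- make_expr(c(4, 9, 16))
  out <- transform_expression(e, "sqrt")
  expect_equal(unname(out$values[1, ]), c(2, 3, 4))
  expect_identical(out$stage, "transformed")
  expect_equal(transform_expression(e, "none")$values, e$values)
  expect_error(transform_expression(make_expr(c(-1, 2, 3)), "sqrt"),
               "g1.*s1")
  # delta method: var(sqrt(Poisson(lambda))) ~ 1/4 regardless of lambda
  set.seed(1)
  pois <- make_expr(matrix(rpois(2000, 50), 1))
  v <- var(transform_expression(pois, "sqrt")$values[1, ])
  expect_gt(v, 0.2); expect_lt(v, 0.3)
})

test_that("latent-factor removal strips broad structure but honours rank", {
  set.seed(2)
  n <- 60; m <- 40
  base <- matrix(rnorm(m * n), m)
  e <- make_expr(base + 5, stage = "transformed")
  out0 <- remove_latent_factors(e, 0)
  expect_equal(out0$values, e$values - rowMeans(e$values),
               ignore_attr = TRUE)
  # rank-1 matrix: removing 1 factor leaves numerical zero
  rank1 <- make_expr(outer(rnorm(m), rnorm(n)), stage = "transformed")
  out1 <- remove_latent_factors(rank1, 1)
  expect_lt(max(abs(out1$values)), 1e-8)
  expect_error(remove_latent_factors(rank1, 2), "rank")
  # planted batch shift across all genes is removed
  batch <- rep(c(0, 3), each = n / 2)
  shifted <- make_expr(base + matrix(batch, m, n, byrow = TRUE),
                       stage = "transformed")
  cleaned <- remove_latent_factors(shifted, 1)
  before <- mean(abs(rowMeans(shifted$values[, batch > 0]) -
                       rowMeans(shifted$values[, batch == 0])))
  after <- mean(abs(rowMeans(cleaned$values[, batch > 0]) -
                      rowMeans(cleaned$values[, batch == 0])))
  expect_lt(after, 0.1 * before)
})

test_that("quantile normalization maps to exact normal scores", {
  expect_equal(quantile_normalize(c(5, 2, 9)),
               qnorm(c(1.5, 0.5, 2.5) / 3))
  expect_equal(round(sort(quantile_normalize(c(5, 2, 9))), 4),
               c(-0.9674, 0, 0.9674))
  # invariance under monotone transforms
  x <- rnorm(50)
  expect_equal(quantile_normalize(x), quantile_normalize(exp(x)))
  # ties share the average-rank score
  qt <- quantile_normalize(c(1, 1, 2))
  expect_equal(qt[1], qt[2])
  expect_equal(qt[1], qnorm((1.5 - 0.5) / 3))
  expect_warning(qc <- quantile_normalize(rep(1, 5)), "constant")
  expect_equal(qc, rep(0, 5))
  # sorted output equals the fixed normal-score vector for that n
  e <- make_expr(matrix(rnorm(30), 1), stage = "factor-removed")
  out <- quantile_normalize(e)
  expect_equal(sort(out$values[1, ]),
               qnorm((seq_len(30) - 0.5) / 30), ignore_attr = TRUE)
  expect_identical(out$stage, "normalized")
})

test_that("relatedness residuals remove family correlation", {
  # all-singleton cohort: exact mean centering
  sim <- simulate_cohort(0, 0, 40, seed = 4)
  vals <- matrix(rnorm(40), 1,
                 dimnames = list("g1", sim$cohort$pedigree$sample_id))
  e <- make_expr(vals, stage = "normalized")
  colnames(e$values) <- sim$cohort$pedigree$sample_id
  e$samples <- sim$cohort$pedigree$sample_id
  out <- grammar_residuals(e, sim$cohort)
  expect_equal(out$values[1, ], vals[1, ] - mean(vals[1, ]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(out$stage, "grammar-residual")

  # strong family variance: within-family ICC collapses
  sim2 <- simulate_cohort(80, 120, 40, seed = 5)
  g2 <- simulate_genotypes(sim2$cohort, sim2$ibd, 3, seed = 6)
  se <- simulate_expression(g2, sim2$cohort,
                            list(gene_spec("g1", var_fam = 4,
                                           var_res = 0.5)), seed = 7)
  blocks <- vamap:::cohort_blocks(sim2$cohort,
                                  se$expression$samples)
  y <- se$expression$values[1, ]
  icc <- function(v) cor(v[blocks$p1], v[blocks$p2])
  expect_gt(icc(y), 0.8)
  eg <- se$expression
  eg$stage <- "normalized"
  res <- grammar_residuals(eg, sim2$cohort)
  # positive family correlation is removed; residualizing a shared pair
  # effect leaves (at most) negative within-pair correlation, exactly as
  # family-mean centering would
  expect_lt(icc(res$values[1, ]), 0.1)
})

test_that("stages refuse out-of-order input", {
  e <- make_expr(c(1, 2, 3))
  expect_error(grammar_residuals(e, simulate_cohort(0, 0, 3)$cohort),
               "stage")
  en <- make_expr(c(1, 2, 3), stage = "normalized")
  expect_error(transform_expression(en, "sqrt"), "stage")
  expect_error(quantile_normalize(make_expr(1:3,
                                            stage = "grammar-residual")),
               "stage")
})
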