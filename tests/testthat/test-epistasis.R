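# Shared fixture: a twin cohort with genotypes; heavier power studies live
# in the acceptance suite.
epi_fixture <- function(seed, n_mz = 75, n_dz = 100, n_single = 50,
                        n_var = 30) {
  sim <- simulate_cohort(n_mz, n_dz, n_single, seed = seed)
  g <- simulate_genotypes(sim$cohort, sim$ibd, n_var, ld_rho = 0.3,
                          seed = seed + 1)
  list(sim = sim, g = g, blocks = vamap:::cohort_blocks(
    sim$cohort, colnames(g$dosage)))
}

test_that("stepwise scan recovers a strong planted interaction and stops", {
  fx <- epi_fixture(41)
  spec <- list(gene_spec("epi",
                         additive = list(list(variant = "v00010",
                                              beta = 0.3)),
                         epistasis = list(v = "v00010", k = "v00025",
                                          share = 0.15),
                         var_fam = 0.2, var_mz = 0.1))
  se <- simulate_expression(fx$g, fx$sim$cohort, spec, seed = 42)
  y <- se$expression$values[1, ]
  cand <- fx$g$dosage[-10, , drop = FALSE]
  hits <- forward_stepwise_epistasis(
    y, fx$g$dosage[10, ], cand, fx$blocks, alpha_bonf = 1e-3,
    positions = fx$g$variants$pos[-10])
  expect_gte(nrow(hits), 1)
  r_proxy <- abs(cor(cand[hits$partner_id[1], ],
                     fx$g$dosage["v00025", ]))
  expect_gt(r_proxy, 0.9)
  expect_equal(sign(hits$signed_variance_share[1]), sign(hits$c_hat[1]))
  expect_lt(abs(hits$signed_variance_share[1] - 0.15), 0.1)
})

test_that("stepwise output is invariant to candidate order", {
  fx <- epi_fixture(43, n_mz = 40, n_dz = 60, n_single = 20, n_var = 15)
  spec <- list(gene_spec("epi", epistasis = list(v = "v00005",
                                                 k = "v00012",
                                                 share = 0.2)))
  se <- simulate_expression(fx$g, fx$sim$cohort, spec, seed = 44)
  y <- se$expression$values[1, ]
  cand <- fx$g$dosage[-5, , drop = FALSE]
  pos <- fx$g$variants$pos[-5]
  h1 <- forward_stepwise_epistasis(y, fx$g$dosage[5, ], cand, fx$blocks,
                                   alpha_bonf = 1e-4, positions = pos)
  ord <- rev(seq_len(nrow(cand)))
  h2 <- forward_stepwise_epistasis(y, fx$g$dosage[5, ],
                                   cand[ord, , drop = FALSE], fx$blocks,
                                   alpha_bonf = 1e-4,
                                   positions = pos[ord])
  expect_identical(h1$partner_id, h2$partner_id)
  expect_equal(h1$lrt_p, h2$lrt_p, tolerance = 1e-8)
})

test_that("null gene yields no hits at the Bonferroni threshold", {
  for (seed in 1:3) {
    fx <- epi_fixture(50 + seed, n_mz = 40, n_dz = 60, n_single = 20,
                      n_var = 20)
    se <- simulate_expression(fx$g, fx$sim$cohort,
                              list(gene_spec("null", var_fam = 0.2)),
                              seed = 60 + seed)
    y <- se$expression$values[1, ]
    hits <- forward_stepwise_epistasis(
      y, fx$g$dosage[3, ], fx$g$dosage[-3, , drop = FALSE], fx$blocks,
      alpha_bonf = 1.98e-8, positions = fx$g$variants$pos[-3])
    expect_equal(nrow(hits), 0)
  }
})

test_that("two independent planted partners are both recovered in order", {
  fx <- epi_fixture(70, n_mz = 100, n_dz = 150, n_single = 100,
                    n_var = 30)
  # partners far apart so LD does not couple them
  sv <- fx$g$dosage[15, ]
  k1 <- fx$g$dosage[1, ]; k2 <- fx$g$dosage[30, ]
  set.seed(71)
  y <- 0.2 * sv + 0.8 * sv * k1 + 0.5 * sv * k2 + rnorm(length(sv))
  names(y) <- colnames(fx$g$dosage)
  hits <- forward_stepwise_epistasis(
    y, sv, fx$g$dosage[-15, , drop = FALSE], fx$blocks,
    alpha_bonf = 1e-4, positions = fx$g$variants$pos[-15])
  expect_gte(nrow(hits), 2)
  prox <- function(id, target) abs(cor(fx$g$dosage[id, ], target))
  expect_gt(prox(hits$partner_id[1], k1), 0.9)   # stronger effect first
  expect_gt(prox(hits$partner_id[2], k2), 0.9)
})

test_that("dominance conditioning removes dominance artifacts, keeps epistasis", {
  fx <- epi_fixture(80, n_mz = 100, n_dz = 150, n_single = 100,
                    n_var = 25)
  sv <- fx$g$dosage[12, ]
  gp_v <- cbind(fx$g$gp$ref[12, ], fx$g$gp$het[12, ], fx$g$gp$alt[12, ])
  removed <- kept <- 0
  for (rep in 1:5) {
    # dominance-only truth: expression depends on het state, no partner
    set.seed(90 + rep)
    y_dom <- 0.8 * (round(sv) == 1) + rnorm(length(sv), 0, 0.6)
    names(y_dom) <- colnames(fx$g$dosage)
    hits <- forward_stepwise_epistasis(
      y_dom, sv, fx$g$dosage[-12, , drop = FALSE], fx$blocks,
      alpha_bonf = 1e-3, positions = fx$g$variants$pos[-12],
      max_steps = 1)
    if (nrow(hits)) {
      filt <- dominance_conditional_filter(
        hits, y_dom, sv, gp_v, fx$g$dosage[-12, , drop = FALSE],
        fx$blocks, alpha_bonf = 1e-3)
      removed <- removed + (nrow(filt) == 0)
    } else removed <- removed + 1   # nothing spurious to begin with
    # genuine interaction survives the same conditioning
    set.seed(190 + rep)
    k <- fx$g$dosage[25, ]
    y_epi <- 0.5 * sv * k + rnorm(length(sv), 0, 0.8)
    names(y_epi) <- colnames(fx$g$dosage)
    hits2 <- forward_stepwise_epistasis(
      y_epi, sv, fx$g$dosage[-12, , drop = FALSE], fx$blocks,
      alpha_bonf = 1e-3, positions = fx$g$variants$pos[-12],
      max_steps = 1)
    if (nrow(hits2)) {
      filt2 <- dominance_conditional_filter(
        hits2, y_epi, sv, gp_v, fx$g$dosage[-12, , drop = FALSE],
        fx$blocks, alpha_bonf = 1e-3)
      kept <- kept + (nrow(filt2) > 0)
    }
  }
  expect_gte(removed, 4)
  expect_gte(kept, 4)
})

test_that("variance share is zero at c = 0 and signed by the coefficient", {
  fx <- epi_fixture(100, n_mz = 30, n_dz = 40, n_single = 20, n_var = 10)
  sv <- fx$g$dosage[2, ]; sk <- fx$g$dosage[8, ]
  set.seed(101)
  y <- 0.4 * sv - 0.5 * sv * sk + rnorm(length(sv))
  X <- cbind(`(Intercept)` = 1, v = sv, b_k = sk, c_k = sv * sk)
  fit <- twin_lmm(y, X, fx$blocks)
  share <- interaction_variance_share(fit, "c_k")
  expect_lt(share, 0)
  fit0 <- fit
  fit0$coefficients["c_k"] <- 0
  expect_equal(interaction_variance_share(fit0, "c_k"), 0)
})
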