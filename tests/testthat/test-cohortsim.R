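test_that("cohort simulation is deterministic and draws IBD at the autosomal rates", {
  a <- simulate_cohort(3, 5, 2, seed = 11)
  b <- simulate_cohort(3, 5, 2, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$ibd$pi_cis[grepl("^MZ", a$ibd$family_id)] == 1))
  expect_error(simulate_cohort(0, 0, 0), "zero")

  big <- simulate_cohort(0, 4000, 0, seed = 5)
  freq <- table(factor(big$ibd$pi_cis, levels = c(0, 0.5, 1))) / 4000
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.03))
})

test_that("genotype simulation respects twin sharing and target frequencies", {
  sim <- simulate_cohort(20, 60, 20, seed = 3)
  g <- simulate_genotypes(sim$cohort, sim$ibd, 200,
                          maf_range = c(0.2, 0.3), ld_rho = 0.6, seed = 4)
  ped <- sim$cohort$pedigree
  # MZ twins carry identical genomes
  mz_fams <- unique(ped$family_id[ped$zygosity == "MZ"])
  for (f in mz_fams[1:5]) {
    idx <- ped$sample_id[ped$family_id == f]
    expect_equal(g$dosage[, idx[1]], g$dosage[, idx[2]],
                 ignore_attr = TRUE)
  }
  # DZ pairs with full cis IBD share cis genotypes (no recombination)
  dz1 <- sim$ibd$family_id[sim$ibd$pi_cis == 1 &
                             grepl("^DZ", sim$ibd$family_id)]
  for (f in head(dz1, 3)) {
    idx <- ped$sample_id[ped$family_id == f]
    expect_equal(g$dosage[, idx[1]], g$dosage[, idx[2]],
                 ignore_attr = TRUE)
  }
  # realized MAFs concentrate around the target range
  expect_gte(mean(g$variants$maf >= 0.15 & g$variants$maf <= 0.35), 0.95)
  # adjacent variants are in LD
  cors <- sapply(1:50, function(v) cor(g$dosage[v, ], g$dosage[v + 1, ]))
  expect_gt(mean(cors), 0.35)
  expect_error(simulate_genotypes(sim$cohort, sim$ibd, 10,
                                  maf_range = c(0.2, 0.6)), "maf_range")
})

test_that("haplotype confounder has complete D-prime but low R2 with its tags", {
  sim <- simulate_cohort(0, 0, 400, seed = 9)
  g <- simulate_genotypes(sim$cohort, sim$ibd, 60,
                          maf_range = c(0.25, 0.35), ld_rho = 0.2, seed = 10)
  hc <- simulate_haplotype_confounder(g, rare_maf = 0.03, seed = 11)
  expect_true(all(hc$dprime >= 0.95))
  expect_true(all(hc$r2 < 0.2))
  # rare allele sits only on haplotypes carrying both tag alleles
  hap <- attr(hc$genotypes, "haplotypes")
  ti <- match(hc$tags, hc$genotypes$variants$variant_id)
  ri <- match(hc$rare_id, hc$genotypes$variants$variant_id)
  on_rare <- which(hap$H[ri, ] == 1)
  expect_true(all(hap$H[ti[1], on_rare] == 1))
  expect_true(all(hap$H[ti[2], on_rare] == 1))
  rare_maf <- mean(hc$genotypes$dosage[ri, ]) / 2
  expect_lt(abs(rare_maf - 0.03), 0.01)
})

test_that("expression simulation realizes target variance structure", {
  sim <- simulate_cohort(100, 150, 100, seed = 21)   # n = 600
  g <- simulate_genotypes(sim$cohort, sim$ibd, 20, seed = 22)
  # pure-noise gene: sample variance near 1 at large n
  sim2 <- simulate_cohort(0, 0, 1000, seed = 23)
  g2 <- simulate_genotypes(sim2$cohort, sim2$ibd, 5, seed = 24)
  se2 <- simulate_expression(g2, sim2$cohort, list(gene_spec("null")),
                             seed = 25)
  expect_true(var(se2$expression$values[1, ]) > 0.9 &&
                var(se2$expression$values[1, ]) < 1.1)

  # planted signed interaction share lands near target
  spec <- list(gene_spec("epi",
                         additive = list(list(variant = "v00003",
                                              beta = 0.3)),
                         epistasis = list(v = "v00003", k = "v00015",
                                          share = 0.05)),
               gene_spec("epineg",
                         epistasis = list(v = "v00003", k = "v00015",
                                          share = -0.05)))
  se <- simulate_expression(g, sim$cohort, spec, seed = 26)
  expect_lt(abs(se$truth$epi$shares$epistasis - 0.05), 0.02)
  expect_lt(abs(se$truth$epineg$shares$epistasis + 0.05), 0.02)
  expect_lt(se$truth$epineg$c, 0)
  expect_error(gene_spec("bad", epistasis = list(v = "a", k = "b",
                                                 share = 0.6)),
               "unrealistic")

  # dominant MZ-shared variance drives within-pair correlation up
  spec3 <- list(gene_spec("fam", var_fam = 3, var_mz = 3,
                          var_res = 0.01))
  se3 <- simulate_expression(g, sim$cohort, spec3, seed = 27)
  blocks <- vamap:::cohort_blocks(sim$cohort, colnames(g$dosage))
  y <- se3$expression$values[1, ]
  mz <- blocks$is_mz
  expect_gt(cor(y[blocks$p1[mz]], y[blocks$p2[mz]]), 0.9)

  # covariance-attributed decomposition reconciles to 1
  expect_lt(abs(sum(se$truth$epi$shares_recon) - 1), 0.02)
  # for independent terms the variance shares agree with the attribution
  spec4 <- list(gene_spec("recon",
                          additive = list(list(variant = "v00010",
                                               beta = 1)),
                          var_fam = 0.3, var_mz = 0.2))
  se4 <- simulate_expression(g, sim$cohort, spec4, seed = 28)
  expect_lt(abs(sum(se4$truth$recon$shares_recon) - 1), 0.02)
  expect_lt(abs(se4$truth$recon$shares$additive -
                  se4$truth$recon$shares_recon[1]), 0.05)
})

test_that("GxE genes show genotype-dependent MZ discordance, epistasis genes do not", {
  sim <- simulate_cohort(200, 0, 0, seed = 31)
  g <- simulate_genotypes(sim$cohort, sim$ibd, 10,
                          maf_range = c(0.4, 0.5), seed = 32)
  spec <- list(
    gene_spec("gxe", gxe = list(variant = "v00002", eta = 1)),
    gene_spec("epi", epistasis = list(v = "v00002", k = "v00008",
                                      share = 0.3)))
  se <- simulate_expression(g, sim$cohort, spec, seed = 33)
  blocks <- vamap:::cohort_blocks(sim$cohort, colnames(g$dosage))
  gshare <- g$dosage["v00002", blocks$p1]
  for (gene in c("gxe", "epi")) {
    y <- se$expression$values[gene, ]
    dif <- abs(y[blocks$p1] - y[blocks$p2])
    spread <- tapply(dif, round(gshare), mean)
    if (gene == "gxe") {
      expect_gt(spread[["2"]], 1.4 * spread[["0"]])
    } else {
      expect_lt(spread[["2"]], 1.4 * spread[["0"]])
    }
  }
})
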