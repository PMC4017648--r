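test_that("VCF genotype probabilities convert to dosages and round-trip", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, with_gp = TRUE, with_ds = TRUE)
  g <- read_genotypes(path)
  expect_s3_class(g, "genotype_table")
  expect_false(g$degenerate_gp)
  # dosage = 0*P(ref) + 1*P(het) + 2*P(alt)
  expect_equal(unname(g$dosage[1, ]), c(1.0, 0.3, 1.8), tolerance = 1e-9)
  expect_equal(g$variants$info, c(0.95, 0.95))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, out)
  g2 <- read_genotypes(out)
  expect_equal(g2$dosage, g$dosage, tolerance = 1e-9)
  expect_equal(g2$gp$het, g$gp$het, tolerance = 1e-9)
  expect_identical(g2$samples, g$samples)
})

test_that("DS-only VCF yields flagged degenerate GP triplets", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, with_gp = FALSE, with_ds = TRUE)
  g <- read_genotypes(path)
  expect_true(g$degenerate_gp)
  # minimal-entropy completion of dosage 0.3 is (0.7, 0.3, 0)
  expect_equal(unname(g$gp$ref[1, 2]), 0.7)
  expect_equal(unname(g$gp$het[1, 2]), 0.3)
  expect_equal(unname(g$gp$alt[1, 2]), 0)
})

test_that("QC filters apply the strict removal thresholds and are idempotent", {
  samples <- paste0("s", 1:100)
  set.seed(42)
  dos <- rbind(
    low_maf = rbinom(100, 2, 0.005),
    at_maf = c(rep(1, 2), rep(0, 98)),          # maf exactly 0.01
    low_info = rbinom(100, 2, 0.3),
    good = rbinom(100, 2, 0.4))
  colnames(dos) <- samples
  variants <- data.frame(variant_id = rownames(dos), chrom = "1",
                         pos = 1:4 * 1000, ref = "A", alt = "G",
                         info = c(1, 0.8, 0.79, 0.99))
  g <- genotype_table(variants, dos + 0)
  ev <- rbind(many_zero = c(rep(0, 12), rpois(88, 5) + 1),
              ok = rpois(100, 5) + 1)
  colnames(ev) <- samples
  e <- expression_table(data.frame(gene_id = rownames(ev), chrom = "1",
                                   tss = 1500, strand = "+"), ev + 0)
  res <- apply_qc_filters(g, e)
  expect_setequal(res$genotypes$variants$variant_id, c("at_maf", "good"))
  expect_identical(res$expression$genes$gene_id, "ok")
  expect_setequal(res$report$id[res$report$type == "variant"],
                  c("low_maf", "low_info"))
  res2 <- apply_qc_filters(res$genotypes, res$expression)
  expect_equal(res2$genotypes$dosage, res$genotypes$dosage)
  expect_equal(nrow(res2$report), 0)
})

test_that("cis window is closed at +/- half-width and trans mask strictly open", {
  pos <- c(499999, 500000, 1500000, 2500000, 2500001,
           6499999, 6500000, 6500001)
  variants <- data.frame(variant_id = paste0("v", seq_along(pos)),
                         chrom = "1", pos = pos, ref = "A", alt = "G",
                         info = 1)
  dos <- matrix(rep(c(0, 1, 2), length.out = 3 * length(pos)),
                nrow = length(pos), dimnames = list(variants$variant_id,
                                                    c("a", "b", "c")))
  g <- genotype_table(variants, dos)
  gene <- data.frame(gene_id = "g", chrom = "1", tss = 1500000,
                     strand = "+")
  cis <- cis_window_variants(g, gene, half_width = 1e6)
  expect_identical(cis, c("v2", "v3", "v4"))   # [500000, 2500000] inclusive
  tr <- trans_mask(g, gene, min_distance = 5e6)
  expect_identical(tr, "v8")  # |d| = 5e6 excluded, 5e6+1 included
  expect_length(intersect(cis, tr), 0)
  # different chromosome is always trans, never cis
  gene2 <- data.frame(gene_id = "g2", chrom = "2", tss = 1500000,
                      strand = "+")
  expect_warning(cis2 <- cis_window_variants(g, gene2), "chromosome")
  expect_length(cis2, 0)
  expect_length(trans_mask(g, gene2), length(pos))
})

test_that("expression and pedigree TSVs round-trip with stage tags", {
  sim <- simulate_cohort(2, 2, 1, seed = 7)
  vals <- matrix(rnorm(2 * 9), 2,
                 dimnames = list(c("g1", "g2"),
                                 sim$cohort$pedigree$sample_id))
  e <- expression_table(data.frame(gene_id = c("g1", "g2"), chrom = "1",
                                   tss = c(100L, 200L), strand = "+"),
                        vals, stage = "normalized")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(e, f)
  e2 <- read_expression_tsv(f)
  expect_equal(e2$values, e$values, tolerance = 1e-12)
  expect_identical(e2$stage, "normalized")
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree_tsv(sim$cohort, fp)
  c2 <- read_pedigree_tsv(fp)
  expect_identical(c2$pedigree$zygosity, sim$cohort$pedigree$zygosity)
})

test_that("containers validate their invariants", {
  expect_error(twin_cohort(data.frame(sample_id = c("a", "b", "c"),
                                      family_id = "f1",
                                      zygosity = "MZ")),
               "at most 2")
  expect_error(twin_cohort(data.frame(sample_id = c("a", "b"),
                                      family_id = c("f1", "f1"),
                                      zygosity = c("MZ", "DZ"))),
               "constant within family")
  expect_error(twin_cohort(data.frame(sample_id = "a", family_id = "f1",
                                      zygosity = "MZ")),
               "singleton")
  v <- data.frame(variant_id = "v1", chrom = "1", pos = 1L, ref = "A",
                  alt = "G")
  d <- matrix(1, 1, 2, dimnames = list("v1", c("a", "b")))
  bad_gp <- list(ref = matrix(0.5, 1, 2), het = matrix(0.4, 1, 2),
                 alt = matrix(0.3, 1, 2))
  expect_error(genotype_table(v, d, bad_gp), "sum to 1")
})
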