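#' Default pipeline configuration
#'
#' Thresholds default to the analysis' standard settings: square-root
#' transform, 50 latent factors for the discovery cohort (20 for
#' replication-style runs), MAF >= 0.01 and imputation info >= 0.8, cis
#' window of +/- 1 Mbp, trans distance > 5 Mbp, 5 shared permutations,
#' Bonferroni interaction threshold 1.98e-8, eQTL entry p < 1e-5, FDR
#' 0.05.
#'
#' @param ... overrides for any default element.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  config <- list(
    seed = 1,
    transform = "sqrt", n_factors = 50,
    maf_min = 0.01, info_min = 0.8, zero_frac_max = 0.10,
    cis_half_width = 1e6, trans_distance = 5e6,
    n_perm = 5, fdr = 0.05, alpha_bonf = 1.98e-8, p_enter = 1e-5,
    max_steps = 10,
    stages = list(preprocess = TRUE, veqtl = TRUE, epistasis = TRUE,
                  gxe = TRUE, vc = FALSE))
  overrides <- list(...)
  config[names(overrides)] <- overrides
  config
}

#' Run the variance-association analysis end to end
#'
#' Sequences preprocessing (transform, latent-factor removal, quantile
#' normalization, relatedness residuals), the v-eQTL scan, the
#' forward-stepwise epistasis scan with dominance conditioning, the
#' MZ-discordance (GxE) tests, and optionally the cis/trans
#' variance-components analysis, writing every stage's table plus a
#' manifest and summary JSON into `out_dir`. Outputs are deterministic
#' under `config$seed`.
#'
#' @param genotypes a [genotype_table()] or path readable by
#'   [read_genotypes()].
#' @param expression an [expression_table()] or TSV path.
#' @param pedigree a [twin_cohort()] or TSV path.
#' @param out_dir output directory (created).
#' @param config list from [pipeline_config()].
#' @param ibd optional IBD table (enables the `vc` stage).
#' @return invisibly, a list with the stage results and the summary.
#' @export
run_pipeline <- function(genotypes, expression, pedigree, out_dir,
                         config = pipeline_config(), ibd = NULL) {
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  if (is.character(pedigree)) pedigree <- read_pedigree_tsv(pedigree)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  summary <- list(seed = config$seed)
  results <- list()

  qc <- apply_qc_filters(genotypes, expression, config$maf_min,
                         config$info_min, config$zero_frac_max)
  summary$qc <- list(variants_kept = nrow(qc$genotypes$variants),
                     genes_kept = nrow(qc$expression$genes),
                     removed = nrow(qc$report))
  g <- qc$genotypes

  e <- qc$expression
  if (isTRUE(stages$preprocess)) {
    if (e$stage == "raw") {
      e <- transform_expression(e, config$transform)
      nf <- min(config$n_factors, min(dim(e$values)) - 1)
      e <- remove_latent_factors(e, nf)
      e <- quantile_normalize(e)
    }
    e_gr <- grammar_residuals(e, pedigree)
    write_expression_tsv(e_gr, file.path(out_dir, "expression_grammar.tsv"))
  } else {
    e_gr <- if (e$stage == "normalized") grammar_residuals(e, pedigree)
            else e
  }
  results$expression <- e

  if (isTRUE(stages$veqtl)) {
    scan <- scan_veqtl(e_gr, g, config$cis_half_width, config$n_perm,
                       seed = config$seed)
    utils::write.table(scan$peaks, file.path(out_dir, "veqtl_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$veqtl <- list(genes_tested = nrow(scan$peaks),
                          significant = sum(scan$peaks$fdr < config$fdr))
    results$veqtl <- scan
  }

  if (isTRUE(stages$epistasis) && isTRUE(stages$veqtl)) {
    sig <- scan$peaks[scan$peaks$fdr < config$fdr, , drop = FALSE]
    hit_rows <- NULL
    for (i in seq_len(nrow(sig))) {
      gid <- sig$gene_id[i]
      grow <- e$genes[e$genes$gene_id == gid, ]
      y <- e$values[match(gid, e$genes$gene_id), ]
      win <- cis_window_variants(g, grow, config$cis_half_width)
      cand_ids <- setdiff(win, sig$variant_id[i])
      if (!length(cand_ids)) next
      vi <- match(sig$variant_id[i], g$variants$variant_id)
      ci <- match(cand_ids, g$variants$variant_id)
      hits <- forward_stepwise_epistasis(
        y, g$dosage[vi, ], g$dosage[ci, , drop = FALSE], pedigree,
        alpha_bonf = config$alpha_bonf, positions = g$variants$pos[ci],
        max_steps = config$max_steps, samples = e$samples)
      gp_v <- cbind(g$gp$ref[vi, ], g$gp$het[vi, ], g$gp$alt[vi, ])
      hits <- dominance_conditional_filter(
        hits, y, g$dosage[vi, ], gp_v, g$dosage[ci, , drop = FALSE],
        pedigree, config$alpha_bonf, samples = e$samples)
      if (nrow(hits))
        hit_rows <- rbind(hit_rows,
                          cbind(gene_id = gid, veqtl_id = sig$variant_id[i],
                                as.data.frame(hits)))
    }
    if (is.null(hit_rows))
      hit_rows <- data.frame(gene_id = character(0),
                             veqtl_id = character(0),
                             partner_id = character(0))
    utils::write.table(hit_rows, file.path(out_dir, "epistasis_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$epistasis <- list(hits = nrow(hit_rows),
                              genes = length(unique(hit_rows$gene_id)))
    results$epistasis <- hit_rows
  }

  if (isTRUE(stages$gxe) && isTRUE(stages$veqtl)) {
    has_mz <- any(pedigree$pedigree$zygosity == "MZ")
    if (has_mz && nrow(scan$peaks)) {
      dp <- vapply(seq_len(nrow(scan$peaks)), function(i) {
        gid <- scan$peaks$gene_id[i]
        y <- e$values[match(gid, e$genes$gene_id), ]
        vi <- match(scan$peaks$variant_id[i], g$variants$variant_id)
        out <- tryCatch(
          suppressWarnings(deqtl_test(y, pedigree, g$dosage[vi, ],
                                      samples = e$samples)),
          error = function(err) NULL)
        if (is.null(out)) NA_real_ else out$p
      }, numeric(1))
      dtab <- data.frame(gene_id = scan$peaks$gene_id,
                         variant_id = scan$peaks$variant_id,
                         p_discordance = dp)
      utils::write.table(dtab, file.path(out_dir, "deqtl.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pok <- dp[!is.na(dp)]
      frac <- if (length(pok) >= 3)
        suppressWarnings(gxe_fraction(pok, config$fdr)) else NULL
      summary$gxe <- list(tested = length(pok),
                          pi1 = if (is.null(frac)) NA else frac$pi1,
                          significant = if (is.null(frac)) NA else
                            frac$n_significant)
      results$gxe <- dtab
    }
  }

  if (isTRUE(stages$vc) && !is.null(ibd)) {
    R <- build_relatedness(pedigree, ibd)
    vc_rows <- NULL
    for (i in seq_len(nrow(e$genes))) {
      y <- e$values[i, ]
      names(y) <- e$samples
      cmp <- tryCatch(
        suppressWarnings(compare_common_environment(y, R, pedigree)),
        error = function(err) NULL)
      if (is.null(cmp)) next
      f <- cmp$cistrans
      vc_rows <- rbind(vc_rows, data.frame(
        gene_id = e$genes$gene_id[i], var_cis = f$var_cis,
        var_trans = f$var_trans, var_cistrans = f$var_cistrans,
        var_env = f$var_env, share_cistrans = f$share_cistrans,
        delta_loglik = cmp$delta_loglik))
    }
    utils::write.table(vc_rows, file.path(out_dir, "variance_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$vc <- list(genes = if (is.null(vc_rows)) 0 else nrow(vc_rows),
                       mean_share = if (is.null(vc_rows)) NA else
                         mean(vc_rows$share_cistrans))
    results$vc <- vc_rows
  }

  manifest <- list(package = "vamap",
                   version = as.character(utils::packageVersion("vamap")),
                   config = config[setdiff(names(config), "stages")],
                   stages = names(Filter(isTRUE, config$stages)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(summary = summary, out_dir = out_dir)))
}
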