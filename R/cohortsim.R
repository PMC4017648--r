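#' Simulate a twin cohort with IBD sharing
#'
#' Generates MZ pairs, DZ pairs and singletons. Each DZ pair's
#' identity-by-descent sharing for the cis region (and, separately, a
#' representative trans region) is drawn from \{0, 0.5, 1\} with
#' probabilities (0.25, 0.5, 0.25), the autosomal expectation under no
#' recombination within the window. MZ pairs share everything (pi = 1).
#'
#' @param n_mz,n_dz,n_single nonnegative counts.
#' @param seed integer seed.
#' @return list with `cohort` (a [twin_cohort()]) and `ibd` (data.frame
#'   `family_id`, `pi_cis`, `pi_trans`; one row per twin family).
#' @export
simulate_cohort <- function(n_mz, n_dz, n_single, seed = 1) {
  stopifnot(n_mz >= 0, n_dz >= 0, n_single >= 0)
  if (n_mz + n_dz + n_single == 0) stop("all counts are zero")
  set.seed(seed)
  fam_mz <- sprintf("MZ%04d", seq_len(n_mz))
  fam_dz <- sprintf("DZ%04d", seq_len(n_dz))
  fam_s <- sprintf("S%04d", seq_len(n_single))
  ped <- rbind(
    if (n_mz) data.frame(sample_id = paste0(rep(fam_mz, each = 2), "_",
                                            1:2),
                         family_id = rep(fam_mz, each = 2), zygosity = "MZ"),
    if (n_dz) data.frame(sample_id = paste0(rep(fam_dz, each = 2), "_",
                                            1:2),
                         family_id = rep(fam_dz, each = 2), zygosity = "DZ"),
    if (n_single) data.frame(sample_id = paste0(fam_s, "_1"),
                             family_id = fam_s, zygosity = "singleton"))
  pi_levels <- c(0, 0.5, 1)
  ibd <- data.frame(
    family_id = c(fam_mz, fam_dz),
    pi_cis = c(rep(1, n_mz),
               sample(pi_levels, n_dz, TRUE, prob = c(0.25, 0.5, 0.25))),
    pi_trans = c(rep(1, n_mz),
                 sample(pi_levels, n_dz, TRUE, prob = c(0.25, 0.5, 0.25))),
    stringsAsFactors = FALSE)
  list(cohort = twin_cohort(ped), ibd = ibd)
}

#' Simulate genotypes on a haplotype backbone
#'
#' Haplotypes are simulated explicitly (two per genome) so that linkage
#' disequilibrium, IBD sharing and haplotype-nested rare alleles are exact
#' constructs; genotype dosage is the haplotype sum. Alleles along a
#' haplotype follow a first-order Markov chain whose transition mixes the
#' variant's target frequency with the previous allele, giving
#' adjacent-variant correlation close to `ld_rho`. MZ twins reuse both
#' haplotype indices; DZ twins share 2, 1 or 0 haplotypes according to
#' `pi_cis` in \{1, 0.5, 0\} — the sharing applies to the whole region (no
#' recombination within the window).
#'
#' Optional genotype-probability blurring (`gp_error`) spreads probability
#' mass onto neighbouring genotype classes and recomputes the dosage from
#' the blurred triplet, emulating imputation uncertainty.
#'
#' @param cohort a [twin_cohort()].
#' @param ibd the IBD table from [simulate_cohort()].
#' @param n_variants number of variants.
#' @param maf_range interval within (0, 0.5] for target allele frequencies.
#' @param ld_rho adjacent-variant LD parameter in [0, 1).
#' @param region list with `chrom`, `start`, `spacing` (bp between
#'   variants).
#' @param gp_error genotype-probability error mass in [0, 0.5).
#' @param seed integer seed.
#' @return a [genotype_table()] carrying the haplotype backbone in
#'   `attr(, "haplotypes")` (founder matrix `H` plus per-sample haplotype
#'   indices `h1`, `h2`).
#' @export
simulate_genotypes <- function(cohort, ibd, n_variants,
                               maf_range = c(0.1, 0.5), ld_rho = 0.5,
                               region = list(chrom = "1", start = 1e6,
                                             spacing = 10000),
                               gp_error = 0, seed = 1) {
  stopifnot(ld_rho >= 0, ld_rho < 1, gp_error >= 0, gp_error < 0.5)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  set.seed(seed)
  ped <- cohort$pedigree
  n_samp <- nrow(ped)
  # assign founder haplotype indices respecting zygosity and cis IBD
  h1 <- integer(n_samp); h2 <- integer(n_samp)
  next_h <- 0L
  new_h <- function() { next_h <<- next_h + 1L; next_h }
  fam_rows <- split(seq_len(n_samp), ped$family_id)
  for (rows in fam_rows) {
    if (length(rows) == 1) {
      h1[rows] <- new_h(); h2[rows] <- new_h()
    } else {
      fid <- ped$family_id[rows[1]]
      pi <- if (ped$zygosity[rows[1]] == "MZ") 1 else
        ibd$pi_cis[match(fid, ibd$family_id)]
      if (is.na(pi)) stop("missing IBD entry for family ", fid)
      a1 <- new_h(); a2 <- new_h()
      h1[rows[1]] <- a1; h2[rows[1]] <- a2
      if (pi == 1) {
        h1[rows[2]] <- a1; h2[rows[2]] <- a2
      } else if (pi == 0.5) {
        h1[rows[2]] <- a1; h2[rows[2]] <- new_h()
      } else {
        h1[rows[2]] <- new_h(); h2[rows[2]] <- new_h()
      }
    }
  }
  n_hap <- next_h
  f <- stats::runif(n_variants, maf_range[1], maf_range[2])
  H <- matrix(0L, n_variants, n_hap)
  H[1, ] <- stats::rbinom(n_hap, 1, f[1])
  for (v in seq_len(n_variants)[-1]) {
    p <- ifelse(H[v - 1, ] == 1, f[v] + ld_rho * (1 - f[v]),
                f[v] * (1 - ld_rho))
    H[v, ] <- stats::rbinom(n_hap, 1, p)
  }
  pos <- region$start + (seq_len(n_variants) - 1L) * region$spacing
  variants <- data.frame(
    variant_id = sprintf("v%05d", seq_len(n_variants)),
    chrom = region$chrom, pos = as.integer(pos),
    ref = "A", alt = "G", info = 1.0, stringsAsFactors = FALSE)
  geno <- H[, h1, drop = FALSE] + H[, h2, drop = FALSE]
  dimnames(geno) <- list(variants$variant_id, ped$sample_id)
  if (gp_error > 0) {
    e <- gp_error
    gp <- list(ref = (geno == 0) * (1 - e) + (geno == 1) * (e / 2),
               het = (geno == 1) * (1 - e) + (geno != 1) * e,
               alt = (geno == 2) * (1 - e) + (geno == 1) * (e / 2))
    dosage <- gp$het + 2 * gp$alt
    gt <- genotype_table(variants, dosage, gp)
  } else {
    gp <- list(ref = 1 * (geno == 0), het = 1 * (geno == 1),
               alt = 1 * (geno == 2))
    gt <- genotype_table(variants, geno + 0, gp)
  }
  attr(gt, "haplotypes") <- list(H = H, h1 = h1, h2 = h2,
                                 samples = ped$sample_id)
  gt
}

#' Plant a rare haplotype-nested eQTL (haplotype confounder)
#'
#' Adds a rare variant whose minor allele occurs only on haplotypes that
#' carry the designated allele at both of two common tagging variants. By
#' construction the rare allele is in complete D' with each tag but low
#' R-squared — the configuration in which a single rare causal eQTL can
#' masquerade as a variance effect or as epistasis between the two tags.
#' Only the rare variant should be given an expression effect downstream.
#'
#' @param g a [genotype_table()] from [simulate_genotypes()] (must carry
#'   the haplotype backbone).
#' @param rare_maf target minor-allele frequency of the rare variant; must
#'   be below the tag MAFs.
#' @param tags character vector of two tagging variant ids; default picks
#'   the two highest-MAF variants at least 10 positions apart.
#' @param seed integer seed.
#' @return list with `genotypes` (updated table), `rare_id`, `tags`,
#'   `dprime` and `r2` (realized LD with each tag).
#' @export
simulate_haplotype_confounder <- function(g, rare_maf = 0.03, tags = NULL,
                                          seed = 1) {
  hap <- attr(g, "haplotypes")
  if (is.null(hap)) stop("genotype table has no haplotype backbone")
  set.seed(seed)
  v <- g$variants
  if (is.null(tags)) {
    ord <- order(-v$maf)
    t1 <- ord[1]
    t2 <- ord[which(abs(v$pos[ord] - v$pos[t1]) >=
                      10 * min(diff(sort(v$pos))))][1]
    if (is.na(t2)) t2 <- ord[2]
    tags <- v$variant_id[c(t1, t2)]
  }
  ti <- match(tags, v$variant_id)
  if (any(v$maf[ti] <= rare_maf))
    stop("rare_maf must be below the tag MAFs")
  usage <- tabulate(c(hap$h1, hap$h2), nbins = ncol(hap$H))
  target <- which(hap$H[ti[1], ] == 1 & hap$H[ti[2], ] == 1)
  if (!length(target))
    stop("no haplotype carries the required allele combination")
  n_alleles <- 2 * length(hap$samples)
  want <- round(rare_maf * n_alleles)
  sel <- sample(target)
  cum <- cumsum(usage[sel])
  k <- which(cum >= want)[1]
  if (is.na(k)) stop("insufficient haplotype background for rare_maf")
  carriers <- sel[seq_len(k)]
  rare_row <- integer(ncol(hap$H))
  rare_row[carriers] <- 1L
  rare_id <- "rare_causal"
  new_var <- data.frame(variant_id = rare_id, chrom = v$chrom[ti[1]],
                        pos = as.integer(mean(v$pos[ti])) + 1L,
                        ref = "A", alt = "G", info = 1.0,
                        maf = NA_real_, stringsAsFactors = FALSE)
  rare_dos <- rare_row[hap$h1] + rare_row[hap$h2]
  # realized LD (haplotype frequencies weighted by usage)
  ld_with <- function(tag_row) {
    pA <- sum(usage * rare_row) / n_alleles
    pB <- sum(usage * tag_row) / n_alleles
    pAB <- sum(usage * rare_row * tag_row) / n_alleles
    D <- pAB - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
      min(pA * pB, (1 - pA) * (1 - pB))
    c(dprime = if (dmax > 0) D / dmax else NA_real_,
      r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  }
  ld1 <- ld_with(hap$H[ti[1], ]); ld2 <- ld_with(hap$H[ti[2], ])
  variants <- rbind(v, new_var)
  dosage <- rbind(g$dosage, rare_dos)
  rownames(dosage) <- variants$variant_id
  gp <- list(ref = rbind(g$gp$ref, 1 * (rare_dos == 0)),
             het = rbind(g$gp$het, 1 * (rare_dos == 1)),
             alt = rbind(g$gp$alt, 1 * (rare_dos == 2)))
  for (nm in names(gp)) rownames(gp[[nm]]) <- variants$variant_id
  variants$maf <- NULL
  gt <- genotype_table(variants, dosage, gp)
  attr(gt, "haplotypes") <- list(H = rbind(hap$H, rare_row), h1 = hap$h1,
                                 h2 = hap$h2, samples = hap$samples)
  list(genotypes = gt, rare_id = rare_id, tags = tags,
       dprime = c(ld1["dprime"], ld2["dprime"]),
       r2 = c(ld1["r2"], ld2["r2"]))
}

#' Specify a simulated gene
#'
#' Builds the per-gene effect specification consumed by
#' [simulate_expression()]. Effects are planted on named variants of the
#' genotype table: additive eQTL (`beta` per alternate-allele dosage), one
#' epistatic pair (target signed variance share or raw coefficient `c`),
#' and a gene-by-environment effect (a linear genotype-by-exposure
#' interaction with an unobserved standard-normal exposure).
#'
#' @param gene_id gene name.
#' @param mu intercept.
#' @param additive list of `list(variant =, beta =)` entries.
#' @param epistasis `list(v =, k =, share =)` (signed target variance
#'   share) or `list(v =, k =, c =)` (raw coefficient).
#' @param gxe `list(variant =, share =)` (target extra-variance share) or
#'   `list(variant =, eta =)` (raw interaction coefficient).
#' @param var_fam,var_mz,var_res variance components.
#' @param chrom,tss gene annotation (defaults resolved against the
#'   genotype table at simulation time).
#' @export
gene_spec <- function(gene_id, mu = 0, additive = NULL, epistasis = NULL,
                      gxe = NULL, var_fam = 0, var_mz = 0, var_res = 1,
                      chrom = NULL, tss = NULL) {
  if (!is.null(epistasis) && !is.null(epistasis$share) &&
      abs(epistasis$share) > 0.5)
    stop("requested interaction variance share above 0.5 is unrealistic")
  list(gene_id = gene_id, mu = mu, additive = additive,
       epistasis = epistasis, gxe = gxe, var_fam = var_fam,
       var_mz = var_mz, var_res = var_res, chrom = chrom, tss = tss)
}

#' Simulate expression phenotypes with planted effects
#'
#' Generates \deqn{y_i = \mu + \sum_a \beta_a S_{ia} + c S_{iv} S_{ik} +
#' \eta g_i E_i + \beta_i + \gamma_i + \epsilon_i} with the family
#' intercept shared within twin pairs and the MZ intercept shared within
#' MZ pairs. The GxE term is a linear genotype-by-exposure interaction:
#' the exposure \eqn{E_i \sim N(0,1)} is drawn independently for every
#' individual (including within MZ pairs), so conditional on genotype the
#' noise is Gaussian with variance \eqn{\sigma^2 + \eta^2 g_i^2} — a bulk
#' scale shift that creates genotype-dependent variance and
#' genotype-dependent within-MZ-pair discordance, while epistasis genes
#' show neither within pairs (twins share both interacting genotypes).
#' Target variance shares are resolved against the realized genotype
#' matrix; the returned truth records the realized share of every planted
#' term.
#'
#' @param g a [genotype_table()].
#' @param cohort a [twin_cohort()] over the same samples.
#' @param spec list of [gene_spec()] entries.
#' @param seed integer seed.
#' @param stage stage tag for the returned table (the generative model
#'   produces analysis-scale phenotypes).
#' @return list with `expression` (an [expression_table()]) and `truth`
#'   (per-gene list of realized coefficients and variance shares).
#' @export
simulate_expression <- function(g, cohort, spec, seed = 1,
                                stage = "normalized") {
  set.seed(seed)
  ped <- cohort$pedigree
  samples <- colnames(g$dosage)
  if (!setequal(ped$sample_id, samples))
    stop("cohort and genotype samples differ")
  ped <- ped[match(samples, ped$sample_id), ]
  n <- length(samples)
  blocks <- cohort_blocks(cohort, samples)
  values <- matrix(0, length(spec), n,
                   dimnames = list(vapply(spec, `[[`, "", "gene_id"),
                                   samples))
  truth <- vector("list", length(spec))
  names(truth) <- rownames(values)
  genes <- data.frame(gene_id = rownames(values),
                      chrom = g$variants$chrom[1],
                      tss = as.integer(stats::median(g$variants$pos)),
                      strand = "+", stringsAsFactors = FALSE)
  for (gi in seq_along(spec)) {
    sp <- spec[[gi]]
    if (!is.null(sp$chrom)) genes$chrom[gi] <- sp$chrom
    if (!is.null(sp$tss)) genes$tss[gi] <- sp$tss
    base <- rep(sp$mu, n)
    add_terms <- NULL
    for (ad in sp$additive) {
      d <- g$dosage[ad$variant, ]
      base <- base + ad$beta * d
      add_terms <- cbind(add_terms, ad$beta * d)
    }
    # random effects
    fam_eff <- numeric(n); mz_eff <- numeric(n)
    if (sp$var_fam > 0) {
      u <- stats::rnorm(length(blocks$p1), 0, sqrt(sp$var_fam))
      fam_eff[blocks$p1] <- u; fam_eff[blocks$p2] <- u
      fam_eff[blocks$singles] <- stats::rnorm(length(blocks$singles), 0,
                                              sqrt(sp$var_fam))
    }
    if (sp$var_mz > 0) {
      v_ <- stats::rnorm(length(blocks$p1), 0, sqrt(sp$var_mz))
      keep <- as.numeric(blocks$is_mz)
      mz_eff[blocks$p1] <- v_ * keep
      mz_eff[blocks$p2] <- v_ * keep
      others <- c(blocks$singles, blocks$p1[!blocks$is_mz],
                  blocks$p2[!blocks$is_mz])
      mz_eff[others] <- stats::rnorm(length(others), 0, sqrt(sp$var_mz))
    }
    # epistasis coefficient resolving the target signed share
    c_val <- 0; prod_term <- NULL
    if (!is.null(sp$epistasis)) {
      sv <- g$dosage[sp$epistasis$v, ]; sk <- g$dosage[sp$epistasis$k, ]
      prod_term <- sv * sk
      vp <- stats::var(prod_term)
      if (vp < 1e-12) stop("degenerate interaction product")
      if (!is.null(sp$epistasis$c)) {
        c_val <- sp$epistasis$c
      } else {
        s_t <- abs(sp$epistasis$share)
        share_at <- function(cc) {
          fx <- base + cc * prod_term
          cc^2 * vp / (stats::var(fx) + sp$var_fam + sp$var_mz + sp$var_res)
        }
        cmax <- sqrt(1e4 * (stats::var(base) + sp$var_fam + sp$var_mz +
                              sp$var_res) / vp) + 1
        c_val <- stats::uniroot(function(cc) share_at(cc) - s_t, c(0, cmax),
                                tol = 1e-10)$root
        c_val <- c_val * sign(sp$epistasis$share)
      }
      base <- base + c_val * prod_term
    }
    # GxE: linear genotype x exposure interaction. Given genotype g the
    # noise is exactly Gaussian with variance var_res + eta^2 g^2 -- a
    # bulk scale shift, which is what a rank-based variance test and the
    # MZ max/min regression are sensitive to.
    eta <- 0; gxe_g <- NULL; gxe_term <- 0
    if (!is.null(sp$gxe)) {
      gxe_g <- g$dosage[sp$gxe$variant, ]
      if (!is.null(sp$gxe$eta)) {
        eta <- sp$gxe$eta
      } else {
        s_t <- sp$gxe$share
        v0 <- stats::var(base) + sp$var_fam + sp$var_mz + sp$var_res
        eta <- sqrt(s_t / (1 - s_t) * v0 / mean(gxe_g^2))
      }
    }
    z <- stats::rnorm(n)
    expo <- stats::rnorm(n)
    if (!is.null(gxe_g)) gxe_term <- eta * gxe_g * expo
    eps <- sqrt(sp$var_res) * z
    y <- base + fam_eff + mz_eff + gxe_term + eps
    values[gi, ] <- y
    vy <- stats::var(y)
    # covariance-attributed decomposition: cov(term, y) / var(y) sums to 1
    # exactly over all realized terms, unlike raw variance ratios, which
    # leave out cross-term covariances
    terms <- cbind(add_terms,
                   if (!is.null(prod_term)) c_val * prod_term,
                   if (!is.null(gxe_g)) gxe_term,
                   fam_eff, mz_eff, eps)
    recon <- apply(terms, 2, function(tt) stats::cov(tt, y) / vy)
    truth[[gi]] <- list(
      mu = sp$mu, c = c_val, eta = eta,
      epistasis = sp$epistasis, gxe = sp$gxe, additive = sp$additive,
      shares = list(
        additive = if (is.null(add_terms)) 0 else
          sum(apply(add_terms, 2, stats::var)) / vy,
        epistasis = if (is.null(prod_term)) 0 else
          sign(c_val) * c_val^2 * stats::var(prod_term) / vy,
        gxe = if (is.null(gxe_g)) 0 else stats::var(gxe_term) / vy,
        fam = sp$var_fam / vy, mz = sp$var_mz / vy,
        residual = sp$var_res / vy),
      shares_recon = recon)
  }
  list(expression = expression_table(genes, values, stage = stage),
       truth = truth)
}

#' Simulate an IBD-structured phenotype for variance-components analysis
#'
#' Draws cis, trans and cis-x-trans genetic values per twin pair with
#' within-pair correlation equal to the pair's IBD sharing (pi_cis,
#' pi_trans and their product respectively; 1 for MZ pairs), an optional
#' common-environment effect shared within every pair, and independent
#' environmental noise. Singletons receive independent draws.
#'
#' @param cohort a [twin_cohort()].
#' @param ibd IBD table from [simulate_cohort()].
#' @param var_cis,var_trans,var_cistrans,var_common,var_env variance
#'   components.
#' @param seed integer seed.
#' @return named numeric vector of phenotypes (sample order = pedigree).
#' @export
simulate_vc_expression <- function(cohort, ibd, var_cis = 0, var_trans = 0,
                                   var_cistrans = 0, var_common = 0,
                                   var_env = 1, seed = 1) {
  set.seed(seed)
  ped <- cohort$pedigree
  n <- nrow(ped)
  blocks <- cohort_blocks(cohort, ped$sample_id)
  y <- stats::rnorm(n, 0, sqrt(var_env))
  fam_pi <- ibd[match(blocks$family_id, ibd$family_id), ]
  pi_c <- ifelse(blocks$is_mz, 1, fam_pi$pi_cis)
  pi_t <- ifelse(blocks$is_mz, 1, fam_pi$pi_trans)
  add_pair_component <- function(y, s2, pi) {
    if (s2 <= 0) return(y)
    z1 <- stats::rnorm(length(blocks$p1)); z2 <- stats::rnorm(length(blocks$p1))
    g1 <- sqrt(s2) * z1
    g2 <- sqrt(s2) * (pi * z1 + sqrt(pmax(1 - pi^2, 0)) * z2)
    y[blocks$p1] <- y[blocks$p1] + g1
    y[blocks$p2] <- y[blocks$p2] + g2
    y[blocks$singles] <- y[blocks$singles] +
      stats::rnorm(length(blocks$singles), 0, sqrt(s2))
    y
  }
  y <- add_pair_component(y, var_cis, pi_c)
  y <- add_pair_component(y, var_trans, pi_t)
  y <- add_pair_component(y, var_cistrans, pi_c * pi_t)
  if (var_common > 0) {
    ce <- stats::rnorm(length(blocks$p1), 0, sqrt(var_common))
    y[blocks$p1] <- y[blocks$p1] + ce
    y[blocks$p2] <- y[blocks$p2] + ce
    y[blocks$singles] <- y[blocks$singles] +
      stats::rnorm(length(blocks$singles), 0, sqrt(var_common))
  }
  names(y) <- ped$sample_id
  y
}
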