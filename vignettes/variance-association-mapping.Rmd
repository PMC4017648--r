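---
title: "Variance association mapping in twin cohorts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance association mapping in twin cohorts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamap)
```

## The scientific problem

A genetic interaction — between two variants (epistasis) or between a
variant and an environmental factor (GxE) — leaves a footprint that a
purely additive analysis misses: the *variance* of the phenotype differs
between genotype groups of one of the interacting loci, even when the
interacting partner is unobserved. vamap implements a two-stage strategy
around this observation for gene expression in twin cohorts: first scan
for variance eQTL (v-eQTL) near each gene, then dissect each v-eQTL into
its possible causes — a cis epistatic partner, a gene-by-environment
interaction, or a haplotype artifact in which a single (often rare) eQTL
nested on a particular haplotype background masquerades as a variance or
interaction signal.

Twins are what make the dissection identifiable. Monozygotic (MZ) twins
share their whole genome, so epistasis and haplotype effects cannot make
expression *differ* between MZ co-twins; genotype-dependent MZ
discordance is therefore evidence of GxE. Dizygotic (DZ) twins share a
cis window entirely, half, or not at all (no recombination over a ~2 Mbp
window), which supports a variance-components decomposition with an
explicit cis-by-trans epistatic term.

## Models

### The twin mixed model

Every interaction test is a likelihood-ratio test between nested linear
mixed models fitted by maximum likelihood. With $S_{iv}$ the dosage of
the v-eQTL and $S_{ik}$ the dosages of previously accepted partners, the
alternative at step $K$ is

$$y_i = \mu + a S_{iv} + \sum_{k<K}(b_k S_{ik} + c_k S_{iv}S_{ik})
      + b_K S_{iK} + c_K S_{iv}S_{iK} + \beta_i + \gamma_i + \varepsilon_i$$

with $\beta_i \sim N(0, \sigma^2_{FAM})$ shared by both members of any
twin pair, $\gamma_i \sim N(0, \sigma^2_{MZ})$ shared only within MZ
pairs, and $\varepsilon_i \sim N(0, \sigma^2)$. The null drops the
$c_K$ term. The dominance variants of these models replace $aS_{iv}$
with separate heterozygote and minor-homozygote probability terms, so an
interaction that merely tags a non-additive effect of the v-eQTL itself
is absorbed before $c_K$ is retested.

The marginal covariance is block diagonal over families with 2x2 blocks,
so `twin_lmm()` profiles the fixed effects by generalized least squares
and the residual scale analytically, and optimizes only the two variance
*ratios* on the log scale (Nelder-Mead, three fixed starting points,
components floored at $10^{-12}$ of the phenotype variance). Because the
block weights depend on a pair only through its zygosity, the likelihood
collapses onto per-class sufficient statistics and each evaluation is
$O(p^2)$, which is what makes the 5,000-replicate calibration study
routine. Identifiability corners are handled explicitly: with no MZ
pairs the MZ ratio is pinned at the floor; with no pairs at all the fit
is ordinary least squares. Tests verify the engine against a dense
multivariate-normal oracle (full covariance, direct 3-parameter
optimization) and against lme4.

### The v-eQTL scan

Expression is prepared as square-root transformed values (RNA-seq counts
are near-Poisson; the square root breaks the mean-variance link),
residualized against latent expression factors, quantile-normalized to
normal scores at offsets $(r - 0.5)/n$, and finally passed through a
relatedness (GRAMMAR) stage: the null twin model is fitted per gene and
the best linear unbiased predictions of the family and MZ intercepts are
subtracted. Per variant, any mean (eQTL) effect is removed by regressing
the phenotype on the posterior probabilities of being a heterozygote and
a minor-allele homozygote; the squared residuals measure each
individual's distance from its genotype-class mean, and a tie-corrected
Spearman correlation between distance and dosage is the variance test.

Five permutations of the distance vector, drawn once per run and reused
for every gene-variant test, preserve the LD structure of the null. The
FDR at threshold $t$ is the permuted count at or below $t$ divided by 5,
over the observed count, evaluated at the per-gene peak p-values, made
monotone nondecreasing and capped at 1. With only five permutations the
estimate is granular near the top of the list: under a complete null the
single smallest observed peak can beat every permuted peak and receive
FDR 0. This is inherent to the published procedure; the global-null
study below quantifies it.

### Dissection of v-eQTL

*Epistasis.* A forward-stepwise scan over the cis window tests every
candidate with the 1-df LRT above, accepts the minimum-p candidate while
it clears a Bonferroni threshold (default $1.98\times10^{-8}$ for a
genome-scale scan; `0.05 / n_tests` when the scan size is known), then
retests each accepted pair under the dominance coding. Effect sizes are
reported as signed variance shares: the variance of the fitted
interaction term over the fixed-effect predictor variance plus all
variance components, signed by $\hat c_K$ (positive means joint
alternate alleles push expression above the additive prediction).

*Replication in unrelated cohorts.* The same interaction is refitted by
OLS with population-indicator covariates; a forward additive eQTL scan
(entry $p < 10^{-5}$) over all cis variants, including rare ones,
supplies conditioning candidates, and an interaction that loses
significance when any single eQTL is added — judged at a Storey q-value
cut over the per-record *worst-case* conditional p — is discarded as a
haplotype effect. Storey's $\pi_0$ is estimated by a cubic-polynomial
smoother over a lambda grid restricted to the observed p-value range,
evaluated at the largest admissible lambda.

*GxE.* For each v-eQTL, the variant's additive mean effect is regressed
out, then per MZ pair the maximum of the two residual values is
regressed on the minimum, the shared genotype, and their product. The
default test is the joint F-test of the genotype main and
min-by-genotype terms. Removing the mean effect first is essential: a
genuine eQTL effect — including the marginal additive effect that any
epistatic interaction induces — otherwise leaks into the genotype term
and breaks the identifying contrast that epistasis cannot create MZ
discordance. With the removal, epistasis-only genes reject at close to
the nominal level while GxE genes are detected; the residual
second-order effect (between-pair variance differences tilt the max-min
slope) keeps the test *near*-uniform rather than exactly uniform under
strong epistasis, which is why the calibration checks use a rate bound
plus a permissive KS level.

*Cis/trans variance components.* With per-family IBD sharing
$\pi_{cis}, \pi_{trans} \in \{0, \tfrac12, 1\}$ (1 for MZ pairs), the
trait covariance is modelled as

$$\Omega = \Pi_{cis}\sigma^2_{cis} + \Pi_{trans}\sigma^2_{trans}
         + \Pi_{cis\text{-}trans}\sigma^2_{cis\text{-}trans}
         + I\sigma^2_e,$$

where $\Pi_{cis\text{-}trans}$ is the Hadamard product of the two
sharing matrices. The reported quantity is the cis-by-trans share
$\sigma^2_{cis\text{-}trans} / (\sigma^2_{cis} + \sigma^2_{trans} +
\sigma^2_{cis\text{-}trans} + \sigma^2_e)$. The competing explanation —
a common environment shared within pairs — replaces the Hadamard term
with a within-pair indicator; the two non-nested models are compared by
log-likelihood difference only.

## The synthetic cohort generator

The generator is first-class, tested code, built so every planted effect
is an exact construct rather than an approximation:

- **Haplotypes, not dosages.** Genomes are two founder haplotypes per
  individual; alleles along a haplotype follow a first-order Markov
  chain mixing each variant's target frequency with the previous allele
  (adjacent-variant LD near `ld_rho`). MZ twins reuse both haplotype
  indices; DZ twins share 2/1/0 haplotypes according to a cis IBD state
  drawn with probabilities (0.25, 0.5, 0.25), the autosomal expectation.
  This makes D'/R² and IBD sharing exact by construction — needed for
  the rare-haplotype confounder (rare allele placed only on haplotypes
  carrying a designated allele pair: complete D', low R²) and for the
  cis-IBD linkage analysis.
- **Expression.** $y = \mu + \sum \beta_a S_a + cS_vS_k + \eta g E +
  \beta_{fam} + \gamma_{mz} + \varepsilon$, with the exposure $E$
  standard normal and independent within MZ pairs. The GxE term is the
  classic linear genotype-by-exposure interaction: conditional on
  genotype the noise is exactly Gaussian with variance
  $\sigma^2 + \eta^2 g^2$. A multiplicative (log-normal) residual-scale
  mechanism was considered and rejected: it shifts variance almost
  entirely through rare tail outliers with an unchanged median, which a
  rank-based variance test is designed to resist, so planted "GxE"
  would be undetectable by the very method under study.
- **Targets, not coefficients.** Interaction and GxE effects are
  specified as target variance shares and resolved against the realized
  genotype matrix (root-finding for the interaction, closed form for
  GxE); the returned truth records realized shares, plus a
  covariance-attributed decomposition that sums to one exactly.

What the generator does *not* emulate: read-level sampling noise,
recombination within the cis window (also assumed absent by the linkage
analysis), population admixture beyond categorical mean shifts, and any
structure in the environmental exposure. Passing tests therefore say the
statistics behave as designed under their own assumptions, not that real
LCL data meets those assumptions.

## Study designs used by the checks

All sizes below are the package's own choices, fixed once:

- LMM oracle equivalence: 20 random instances, $n \le 30$, mixed
  MZ/DZ/singletons; log-likelihood within $10^{-4}$, fixed effects
  within $10^{-3}$.
- LRT calibration: 5,000 null replicates on a 134 MZ + 166 DZ + 100
  singleton cohort ($n = 700$) with family/MZ variance 0.3/0.2.
- v-eQTL scan: 200 genes x 50 variants on a half-scale cohort (67 MZ +
  96 DZ + 50 singletons, $n = 376$); planted runs give 10% of genes a
  GxE variance effect at share 0.4 — a strong, actually detectable
  effect at this $n$ (about 70% per-gene power), reflecting that
  discovered v-eQTL in practice are the detected tail, not typical
  loci. (At share 0.25 the same scan has only ~15% power, which would
  make a false-discovery *proportion* a ratio of two small counts.)
- Interaction recovery: planted signed share +0.05 at $n = 800$ with
  100 candidates at MAF 0.08-0.2. The low-frequency design matters: a
  product term $S_vS_k$ is strongly collinear with its margins at
  common MAF, so only its partial variance is detectable; at these
  frequencies the partial signal supports reliable selection at
  $0.05/99$.
- Haplotype screening: 462 unrelated samples; 30 artifact records whose
  rare nested eQTL (effect 1.5 on a MAF-0.04 allele) induces a
  significant apparent interaction between its two common tags, against
  30 genuine interactions — the population the conditional-eQTL screen
  actually receives.
- Discordance separation: 134 MZ pairs, planted GxE and epistasis at
  share 0.3 with family/MZ variance present.
- Variance components: 150 MZ + 300 DZ pairs; cis/trans/cis-by-trans
  variance 0.2/0.2/0.6 over environmental 1 (true share 0.3).

## Numerical conventions and edge cases

- Coordinates are 1-based; the cis window is closed
  ($|pos - TSS| \le 1$ Mbp), the trans region strictly open
  ($> 5$ Mbp) or another chromosome; windows at chromosome ends are
  truncated, not dropped.
- QC removals are strict inequalities (MAF $< 0.01$, info $< 0.8$,
  zero fraction $> 0.10$); a variant exactly at a threshold survives.
- A dosage-only genotype source receives the minimal-entropy
  probability triplet and is flagged; operations that need heterozygote
  probabilities accept it but the dominance filter marks such hits
  untestable rather than dropping them.
- Quantile normalization uses average ranks for ties; constant genes
  become zeros with a warning.
- Peak and stepwise ties break by genomic position, making scans
  invariant to candidate order.
- Spearman p-values use the $t$ approximation on $n-2$ df; the
  mixed-model LRT uses $\chi^2_1$ with no boundary correction since the
  interaction coefficient is unconstrained.
- Storey's estimate falls back to Benjamini-Hochberg ($\pi_0 = 1$) with
  a warning below 20 p-values or when the restricted lambda grid is too
  short for the cubic smoother.
- Latent-factor removal centers genes; protected covariates are
  regressed out of the factors (the alternative — regressing them out of
  the data — is deliberately not done, so their signal survives).

## Known limitations

- The permutation FDR with five permutations is granular at the top of
  the list; with a few hundred genes a single null gene occasionally
  receives FDR 0 (about one run in ten at the null-study size above).
- The relatedness stage's conditional residuals carry negative
  within-pair correlation (exactly as family-mean centering would); the
  shared-permutation null absorbs this in practice but the scan's
  per-variant p-values are not exact twin-aware p-values.
- The discordance test is near-calibrated, not exactly calibrated,
  under strong epistasis (see above).
- Trans-epistasis scanning reuses the cis machinery over the trans mask;
  no specific power tuning was done for it.
- The variance-components model assumes the supplied IBD states are
  known, as the simulator guarantees; with estimated IBD the shares
  would be attenuated.
- At a few hundred twin pairs the profiled likelihood of the
  cis/trans/cis-by-trans split is nearly flat: per-gene share estimates
  spread widely (SD around 0.14 at 450 pairs), the nonnegativity
  constraint biases the cis-by-trans share downward when the flanking
  components are small, and under a pure-noise model single genetic
  components occasionally exceed 5% of the total. These are properties
  of constrained ML on this covariance family at this sample size —
  fits started at the generative truth converge to the same optima —
  so per-gene shares should be read as noisy screens, not point
  estimates.
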