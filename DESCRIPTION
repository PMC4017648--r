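Package: vamap
Title: Variance Association Mapping of Gene Expression in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects variance quantitative trait loci (v-eQTL) for gene
    expression and dissects the interactions that create them. Provides a
    squared-residual Spearman scan with a shared-permutation false discovery
    rate, a twin-aware linear mixed model for forward-stepwise discovery of
    cis epistasis with dominance conditioning, replication machinery for
    unrelated cohorts including conditional-eQTL screening of haplotype
    effects and Storey q-value summaries, a monozygotic-twin discordance test
    for gene-by-environment interaction, and a cis/trans/cis-by-trans
    variance-components model built on identity-by-descent sharing. A
    truth-tagged synthetic twin-cohort simulator exercises the whole pipeline
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
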