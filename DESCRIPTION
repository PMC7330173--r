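Package: discomod
Title: Discordant Sibling-Pair Multi-Omic Modifier Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discovering candidate phenotype-modifier
    signals in small cohorts of phenotype-discordant sibling pairs, as used in
    studies of cerebral X-linked adrenoleukodystrophy (CALD). Provides a
    four-category genotype discordance engine with exact cross-family (upset)
    intersection, haploblock grouping and mitochondrial heteroplasmy
    discordance; APOE epsilon-allele calling and candidate-allele segregation
    checks; per-feature family-cofactor linear-model scans over lipidomic,
    transcriptomic, proteomic and DNA-methylation matrices with
    multiple-testing correction, CpG delta-beta filtering and differentially
    methylated region calling; per-feature variance partitioning and
    leave-families-out sensitivity analysis; and cross-platform gene-level
    integration with per-family log2-fold-change matrices, PCA and clustering.
    A synthetic-cohort simulator with planted modifier alleles and planted
    phenotype effects makes every stage testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
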