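Package: qtsmap
Title: Association Mapping of Quantitative Trait SSR Loci with Epistasis
    and Environment Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-linear-model association mapping for inbred panels
    genotyped at biallelic presence/absence marker loci and phenotyped in
    multi-environment trials. Detects individual loci and locus pairs with
    additive, additive-by-additive epistasis, and environment-interaction
    effects on quantitative traits; controls the experiment-wise type I
    error by permutation; estimates variance components by REML or
    MINQUE(1); predicts random locus effects (BLUP) with significance;
    partitions heritability into additive, epistasis and
    genotype-by-environment categories; classifies loci by
    cross-environment stability; and exports locus-interaction networks.
    Includes a forward simulator of the phenotype model so every stage is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
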