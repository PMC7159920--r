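Package: popconfound
Title: Simulating and Diagnosing Population-Phenomena Bias in Genotype-Phenotype Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of multi-generation genotyped cohorts with
    population stratification, dynastic (genetic-nurture) effects, and
    assortative mating, together with the estimators these phenomena bias:
    GREML SNP heritability and genetic correlation via average-information
    REML, Haseman-Elston regression, bivariate heritability with
    Monte-Carlo standard errors, polygenic-score construction with
    p-value thresholding and clumping, nontransmitted-allele scores, and
    mother-father-offspring trio attenuation analyses with bootstrap and
    seemingly-unrelated-regression difference tests. Includes diagnostics
    for spousal correlation, principal-component adjustment, and
    negative-control phenotypes, plus writers for PLINK-style and GCTA
    GRM file formats.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
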