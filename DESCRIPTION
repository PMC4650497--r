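Package: acthkinetics
Title: Multilevel Analysis of Longitudinal ACTH-Challenge Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing repeated-measures biological and
    transcriptomic data collected around a pharmacological
    adrenocorticotropic-hormone (ACTH) challenge. Implements the
    multilevel split of an observation matrix into offset, between-animal
    and within-animal components, multilevel PCA/PLS and sparse PLS with
    per-component variable selection, paired time-course differential
    testing with Bonferroni or Benjamini-Hochberg control,
    duplicate-probe consolidation, Ward clustering of kinetic profiles,
    per-gene linear mixed models adjusting for leukocyte composition, and
    Fisher over-representation tests. A synthetic-data module generates
    longitudinal datasets with known ground truth (planted kinetic
    clusters, batch shifts, animal random effects) so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    mixOmics,
    limma,
    ape,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
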