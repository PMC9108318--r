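Package: hypoxbeta
Title: Community Assembly Analysis of Coastal eDNA Metabarcoding Data
    Under Seasonal Hypoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing presence/absence fish community data from
    monthly environmental DNA (eDNA) metabarcoding surveys of a stratified
    coastal bay sampled at two water layers (surface and bottom).  The
    package classifies months into hypoxia and normoxia seasons from
    dissolved-oxygen profiles, ordinates environments (PCA) and species
    composition (Jaccard dissimilarity, nonmetric multidimensional
    scaling), partitions compositional variation with a permutational
    multivariate ANOVA implemented from the distance-partitioning
    definition, evaluates pairwise dissimilarities against a fixed-fixed
    (row- and column-sum preserving) matrix-swap null model run separately
    per month, and fits hierarchical generalized linear mixed models for
    species richness and species occurrence with species-specific random
    coefficients.  A configurable metacommunity simulator generates
    synthetic detection, metadata, and environment tables under species
    sorting, neutral-avoidance, and null assembly scenarios so that the
    whole pipeline can be exercised and calibrated without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmmTMB,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
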