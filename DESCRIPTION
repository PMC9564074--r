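Package: gutorg
Title: Correlation-Network Organization Analysis of Gut Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a reproducible pipeline for studying the
    "organization" of a gut microbial community from genus-level count
    tables: significance-filtered Spearman correlation networks per
    experimental group with spectral clustering of taxa, bootstrap
    inference on five global network-topology statistics (density,
    degree-distribution Shannon entropy, Freeman degree centralization,
    degree heterogeneity, clustering coefficient), community-level group
    comparisons (Bray-Curtis PERMANOVA, pairwise Adonis, Mann-Whitney,
    one-way ANOVA with Tukey HSD), nonparametric differential-abundance
    summaries with principal-component projections, and a
    Benjamini-Yekutieli-filtered multi-omic correlation network linking
    genera, metabolic pathways, bone phenotypes and blood pressure. A
    seeded logistic-normal/multinomial generator with planted correlation
    blocks, planted effects and taxon-linked phenotypes provides fully
    synthetic data with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
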