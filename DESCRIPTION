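Package: cooccurnet
Title: Co-Occurrence Networks and Ordination Concordance for Microbiome
    Feature Tables
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for relative-abundance feature tables
    (carbohydrate-active gene families and taxonomic orders across
    metagenome samples): prevalence/abundance screening of major features,
    Bray-Curtis ordination with ANOSIM and one-way ANOVA group tests,
    Procrustes concordance between ordinations with a permutation test,
    robust Spearman co-occurrence network inference with multiple-testing
    correction, Erdos-Renyi null-model topology comparison, Louvain module
    detection, and module co-occurrence incidence statistics.  Includes a
    Gaussian-copula synthetic-data generator with planted correlation
    blocks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
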