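Package: cheesevirome
Title: Viral Community Dynamics of Smear-Ripened Cheese Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building species-level viral operational taxonomic
    unit (vOTU) catalogs from assembled metavirome contigs and for analysing
    viral community succession on smear-ripened cheese surfaces. Implements
    chimera removal and greedy dereplication based on an identity-by-coverage
    alignment score, a union rule over viral detection tool reports, dairy
    phage reference matching with host-genus override, rarefaction and
    coverage normalization of count tables, ecological statistics (Shannon
    diversity, Bray-Curtis ordination, PERMANOVA, Mantel and Kruskal-Wallis
    permutation tests, complete-linkage profile clustering), a negative
    binomial Wald test for differential abundance, presence/absence
    persistence analysis across production years, and a fully seeded
    synthetic community generator with recorded ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
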