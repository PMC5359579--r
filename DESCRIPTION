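Package: phylocomm
Title: Phylogenetic Community Ecology of 16S rRNA Clone Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete community-phylogenetics workflow for archaeal and
    bacterial 16S rRNA clone-library surveys: sequence quality filtering,
    distance-based OTU clustering at fixed identity thresholds,
    occupancy-abundance regression, alpha diversity (Shannon-Wiener, Faith
    phylogenetic diversity with rarefaction over random subsamples),
    phylogenetic species variability with randomization null models,
    weighted UniFrac beta diversity with principal coordinates analysis and
    permutational MANOVA, Dufrene-Legendre indicator value analysis,
    multivariate regression trees against environmental covariates, and
    Spearman co-occurrence networks with Louvain modularity and Fisher
    module-habitat tests.  A synthetic-community generator reproduces the
    statistical structure of a multi-habitat clone-library survey so every
    stage can be exercised without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
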