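Package: rumennet
Title: Diversity and Co-Occurrence Network Analysis of Multi-Domain Rumen Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing genus-level count tables of the four rumen microbial
    domains (bacteria, archaea, ciliate protozoa, anaerobic fungi) across dietary
    treatments. Implements alpha diversity (Simpson 1-D, richness, Pielou evenness),
    Bray-Curtis dissimilarity with nonmetric multidimensional scaling and PERMANOVA,
    and - centrally - sparse Gaussian graphical model estimation of taxon co-occurrence
    networks: pairwise-complete correlation, nearest positive-definite repair, graphical
    lasso over a tuning-parameter path with Extended BIC model selection, and conversion
    to partial correlations. Downstream network statistics include weighted betweenness
    centrality, hub detection, a binomial vicariance test of within-domain edge
    enrichment, and domain edge densities. A synthetic-data generator produces
    study-shaped multi-domain counts from a known sparse latent Gaussian model with
    planted diet effects, so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    igraph,
    vegan,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
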