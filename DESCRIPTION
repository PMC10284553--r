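Package: ecoweave
Title: Research Weaving of the Ecological Complexity Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for "research weaving" of a scientific
    literature: lexicon-based quantification of complexity-science features
    in article full texts, community-ecology style comparisons of article
    groups (Hill diversity, Bray-Curtis dissimilarity, multivariate
    dispersion, indicator-feature permutation tests), latent Dirichlet
    allocation topic modelling with highest-density-interval top-word
    selection, article-feature co-occurrence networks with a
    dyadic-independent exponential random graph model, co-citation network
    clustering, a catalogue of complexity metrics, and a synthetic corpus
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    vegan,
    mclust,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
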