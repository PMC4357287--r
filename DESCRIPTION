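Package: plastevol
Title: Comparative Analysis of a Developmental Polyphenism, Morphological
    Disparity, and Evolutionary Rates on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking a binary developmental polyphenism to
    morphological diversification across a phylogeny. Covers geometric
    morphometrics of fixed 2-D landmarks (generalized Procrustes analysis,
    Procrustes form space, standard and phylogenetic PCA), morphospace
    disparity with rarefaction and bootstrap tests, two-state continuous-time
    Markov inference and stochastic character mapping with discretized rate
    and bias priors, multi-rate Brownian-motion model selection (AICc, LRT)
    and reversible-jump MCMC sampling of branch-specific rates, phylogenetic
    correlation of discrete and ordinal traits under the threshold model and
    a constant-variance random-walk model with Bayes-factor comparison, and
    exact tests for environmental-induction count tables. Includes a
    synthetic-data generator producing every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    coda,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phytools,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
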