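Package: commdiv
Title: Species Diversity and Genetic Structure in Tree Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of plot-level species diversity and the genetic
    structure of dominant binary (AFLP-type) markers in forest tree
    communities.  Provides Hill-number diversity profiles for species
    abundances and per-locus genetic variants with small-sample bias
    correction, a Bayesian F_ST outlier scan for dominant loci
    (multinomial-Dirichlet model with reversible-jump MCMC over
    locus-specific effects), the Gregorius covariation statistic C with
    one-sided permutation tests, the population differentiation parameter
    delta with a reassignment permutation test, a staged multiple-testing
    candidate-selection procedure, and a seeded synthetic-data generator
    emulating a multi-plot tree-community study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
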