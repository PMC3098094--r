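Package: scimmr
Title: Unsupervised Clustering of Metagenomic Sequences with Interpolated
    Markov Models
Version: 0.1.0
Authors@R:
    person("scimmr", "developers", email = "scimmr@example.org",
           role = c("aut", "cre"))
Description: Clusters anonymous metagenomic reads or contigs by their
    (unknown) source genome. One interpolated context model (ICM) -- a
    probabilistic decision tree over informative context positions with
    chi-square weighted interpolation -- is trained per cluster, and a
    hard-assignment classification-EM loop alternates model re-training
    with maximum-posterior reassignment to locally maximise the
    classification maximum likelihood (CML) criterion. Includes
    composition-based initialisers (k-mer/PCA/normalized-cut bisection and
    a fixed-order Markov MCMC), seeding from supervised taxonomic
    classifications with an abundance filter, bp-weighted recall/precision
    and adjusted Rand evaluation, and a self-contained metagenome read
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
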