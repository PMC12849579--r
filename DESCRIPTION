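Package: mtselect
Title: Multi-Trait Genomic Selection Indices with Relatedness Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selection of a fixed number of breeding candidates from
    multi-trait best linear unbiased estimates (BLUEs) under control of
    genomic relatedness. Implements a quadratic-programming multi-trait
    selection index (QPMSI) that maximizes summed standardized genetic
    merit penalized by the group's genomic relationship (x'Gx), and its
    linear baseline (LPMSI), both subject to a cardinality constraint and
    per-trait minimum-gain constraints. Includes construction of the
    genomic relationship matrix from marker dosages, an exact
    branch-and-bound solver for the binary quadratic program, evaluation
    metrics (mean gain, variance of the mean, gain-to-relatedness ratio,
    mean pairwise relatedness) with relative-efficiency comparisons, and a
    sib-family simulator for correlated multi-trait data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
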