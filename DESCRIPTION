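Package: shrubmf
Title: Multitrophic Community Assembly, Multifunctionality and Functional
    Trade-Offs Along Shrub Expansion Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical pipeline linking soil multitrophic community assembly
    to ecosystem multifunctionality and functional trade-offs across
    successional stages of shrub expansion into grassland. Implements
    abundant/rare taxon partitioning with multivariate cutoff level analysis,
    null-model inference of assembly processes (beta nearest taxon index and
    abundance-based Raup-Crick with a five-way process classification),
    five complementary multifunctionality indices over a 208-variable
    function registry, a per-sample functional trade-off intensity based on
    distance to the 1:1 line, and driver attribution via variance inflation
    screening, redundancy analysis, permutation forward selection and
    hierarchical partitioning. A synthetic-data generator emulating the
    3-stage x 5-replicate study design makes every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    biomformat,
    jsonlite,
    optparse
Config/testthat/edition: 3
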