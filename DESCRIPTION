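Package: nirmreg
Title: Bayesian Semiparametric Regression for Amino Acid Property Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects conserved and radically changing codon sites in
    protein-coding alignments by regressing observed on expected
    physicochemical amino acid property distances. The matrix of regression
    coefficients receives a nested infinite relational model prior (a nested
    Dirichlet process with a spike-and-slab base measure), so correlated
    properties are clustered together and, within each property cluster,
    sites with similar coefficients are grouped. Inference uses a truncated
    stick-breaking blocked Gibbs sampler. Includes the distance computation
    layer (codon neighborhoods, expected and observed per-site distances,
    Fitch parsimony fallback for ancestral sequences), label-invariant
    posterior co-clustering summaries, and generators for block-structured
    and sequence-level simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
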