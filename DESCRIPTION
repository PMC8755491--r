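Package: domainer
Title: Topology-Partitioned dN/dS and Expression-Rate Correlations for
    Transmembrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates separate nonsynonymous/synonymous divergence ratios
    (dN/dS) for the intracellular, transmembrane and extracellular portions
    of transmembrane protein codon alignments, and tests whether the
    expression level-evolutionary rate (E-R) anticorrelation differs between
    the domain classes. Provides reciprocal-best-hit ortholog pairing,
    protein-guided codon alignment, membrane-topology partitioning of
    alignment columns, two interchangeable dN/dS engines (Nei-Gojobori 1986
    counting and Goldman-Yang M0 maximum likelihood), Spearman correlation
    with abundance, Fisher r-to-z comparison of correlation coefficients,
    exact binomial ordering tests, abundance terciles and multi-tissue
    sweeps, plus a codon-substitution simulator with domain-specific omega
    and copula-controlled expression-rate rank correlations for ground-truth
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
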