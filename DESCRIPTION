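Package: rarepinpoint
Title: Pinpointing Rare Causal Variants in Case-Control Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant association testing and causal-variant
    prioritisation for case-control sequencing data. Implements the adaptive
    combination of P-values (ADA) test, which truncates per-site Fisher mid-P
    values at a grid of thresholds, calibrates the best threshold by
    permutation, and selects the variants below the optimal threshold; the
    SKAT and burden score tests (Davies/Imhof tail probabilities with a
    Liu-type moment fallback and an optional small-sample adjustment for
    binary traits); and backward elimination on random variant subsamples
    (BE-SKAT, BE-BURDEN) with return-count partitioning. A coalescent-style
    haplotype simulator with a population-attributable-risk penetrance model
    and a true/false-positive evaluation harness support benchmarking the
    three selection strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
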