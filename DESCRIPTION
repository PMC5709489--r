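Package: multibarcode
Title: Multilocus DNA Barcoding, Coalescent Power Simulation and
    Bayes-Factor Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species identification from many independent nuclear
    loci rather than a single barcode gene. Provides a multilocus alignment
    data model with p-distance, locus ranking and panel selection; barcoding
    gap profiles as a function of the number of loci; identification
    criteria (all-species-barcodes, best-close-match with optimized
    threshold) and their success rates under locus resampling; a
    two-population isolation-with-migration structured-coalescent simulator
    with Jukes-Cantor finite-sites mutation for power studies; and a
    three-step barcoding pipeline (distance screen, quartet species tree
    from neighbor-joining gene trees, Bayes-factor species delimitation via
    a composite pairwise-difference coalescent likelihood with path-sampling
    marginal likelihoods on the Kass-Raftery scale).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
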