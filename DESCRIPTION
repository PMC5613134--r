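Package: hybridgs
Title: Genomic Prediction of Hybrid Performance from Incomplete Factorial Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-kernel genomic prediction of hybrid performance for
    two-pool hybrid breeding programs (e.g. sunflower maintainer x restorer
    crosses). Reads parental SNP genotypes, collapses redundant markers,
    infers hybrid genotypes, builds transmitted-allele kinships (additive,
    female-by-male interaction, Hadamard epistasis, pathway-subset and
    VanRaden kernels), fits multi-kernel linear mixed models by restricted
    maximum likelihood with best linear unbiased prediction of tested and
    untested parents, and evaluates predictive ability under two
    cross-validation schemes (random hybrids, held-out parents). Includes
    per-environment spatial adjustment of plot phenotypes, Wricke ecovalence
    stability screening, and a seeded generator of complete synthetic
    factorial studies with retained ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
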