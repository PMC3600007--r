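Package: simpool
Title: Similarity-Based Rare-Variant Association Tests with Pooling
    Strategies
Version: 0.3.1
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Similarity-based association tests for rare genetic variants
    in a genomic region: multivariate distance matrix regression (MDMR),
    the sequence kernel association test (SKAT), a multi-site U-test and
    the kernel-based association test (KBAT), each combined with either
    Beta-density minor-allele-frequency weighting or super-locus
    collapsing of rare variants. Significance is assessed by permutation
    of case/control labels. Includes Eigenstrat-style principal-component
    stratification adjustment with covariate residualisation, a synthetic
    genotype/phenotype generator for four causal disease architectures
    plus a null model, and a harness that estimates empirical type-I
    error and power-versus-significance curves for comparing the pooling
    strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
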