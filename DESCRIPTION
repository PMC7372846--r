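Package: hegwas
Title: Semi-Parallel Logistic-Regression GWAS over Approximate Homomorphic Encryption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A leveled approximate homomorphic-encryption scheme (an RNS variant of
    CKKS with decomposition-plus-special-modulus key switching) together with the
    packed SIMD circuit that fits a covariate-only logistic model under encryption
    and then computes one-step-Newton effect estimates, Wald statistics and p-values
    for thousands of SNPs simultaneously. Includes an exact plaintext slot emulator
    with identical level and scale bookkeeping, clear-text oracles (full per-SNP
    logistic regression and the plaintext semi-parallel algorithm), a level and
    modulus planner with the published parameter presets, a synthetic
    genotype-phenotype generator, and decryption-side reconstruction of association
    statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
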