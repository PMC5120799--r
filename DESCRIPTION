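Package: dhgp
Title: QTL Mapping and Genomic Prediction in Biparental Doubled Haploid
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for seed-quality trait genetics
    in biparental doubled haploid (DH) crop populations. Provides a DH
    population simulator (Haldane crossover model, multi-environment RCBD
    trials, configurable QTL architectures), SNP marker quality control with
    genetic-bin construction and LD pruning, adjusted entry means (BLUEs),
    variance components and broad-sense heritability, a cofactor-based
    genome-wide QTL scan with BIC stepwise cofactor selection and
    Benjamini-Hochberg FDR control, four genome-wide prediction models
    (RR-BLUP, GBLUP, BayesCpi with a compiled Gibbs sampler, and the
    epistatic extension EG-BLUP), and a cross-validation engine supporting
    training-size, marker-density and environment-number sweeps plus
    independent-population validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    lme4
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
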