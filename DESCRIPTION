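Package: brainage
Title: Age-Related Mean and Dispersion Changes in Brain Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A per-region analysis pipeline for bulk brain transcriptomes
    that asks how donor age shapes both the mean and the dispersion of gene
    expression. It covers region-wise normalization and low-expression
    filtering; a two-step hidden-factor correction that protects the age
    signal by discarding age-correlated latent factors before
    residualization; per-gene linear age regression with
    Benjamini-Hochberg tiers, direction calls, subsampling robustness and
    cross-region rank concordance; pathway-level factor association with
    Bonferroni control; genotype-by-age interaction scans from VCF
    genotypes; univariate Levene tests for differential variability
    between age groups and a multivariate generalization based on robust
    Mahalanobis distances with a minimum covariance determinant estimator;
    and a ground-truth simulator so every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
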