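Package: resectvox
Title: Voxelwise Statistics for Localizing Practice Variation in Brain Tumor Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to localize differences in extent of brain-tumor resection
    between two surgical cohorts from registered binary tumor and residue masks.
    Implements three voxelwise statistical methods: a permutation test on
    risk-minus values with a pooled exact-rational null histogram, Fisher's
    exact test with an explicitly constructed exact null histogram of
    attainable p-values and the corresponding q-value estimator, and a
    hierarchical Bayesian binomial model with partial pooling scored by the
    largest centered credible interval of the between-cohort difference that
    excludes zero. Includes a spherical synthetic-cohort simulator with a
    configurable surgical-avoidance region, count-map aggregation and
    downsampling for NIfTI mask cohorts, and a benchmarking harness producing
    observed-FDR, ROC and precision-recall curves with repetition confidence
    bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    rjags,
    coda,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
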