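Package: litterlab
Title: Home-Field Advantage Statistics and LC-MS Metabolomics Pipelines
    for Litter Decomposition Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reciprocal litter-transplant decomposition
    experiments: the additional-decomposition-at-home (ADH) home-field
    advantage statistic with replicate resampling and one-sample t tests;
    calibration of decomposition cell means to published marginal
    summaries by equality-constrained least squares; factorial linear
    models of litter mass remaining with AIC stepwise selection and
    sequential (Type I) sums-of-squares tables; untargeted LC-MS
    feature-matrix post-processing (blank signal-to-noise, pooled-QC
    coefficient of variation and co-elution autocorrelation filters),
    PCA, permutation PERMANOVA and PLS-DA variable-importance ranking;
    and CHO molecular-formula enumeration with adduct mass arithmetic for
    feature dereplication. Seeded synthetic-data generators emit litterbag
    designs and feature matrices with known ground truth so every stage
    of the pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
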