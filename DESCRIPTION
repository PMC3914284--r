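Package: modalFuse
Title: Fusion of Separate Unimodal Cohorts by Class-Conditional Imputation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Merges feature tables from separate patient cohorts (different
    samples, different modalities, shared binary disease class) into one
    block-sparse unified table and densifies it with simple per-feature,
    per-class imputation schemes (mean, random normal, uniform, bootstrap).
    Composite biomarkers are then screened jointly for predictive performance
    and selection stability: colinearity filtering by mean absolute
    correlation, recursive feature elimination with balanced random forests
    under repeated stratified cross-validation scored by rank AUC,
    feature-frequency and importance-rank stability analyses, and PCA/LDA
    screening with leave-one-out accuracy and coefficient-stability
    indicators. Includes a synthetic two-cohort generator with planted
    informative features for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, DimensionReduction, FeatureExtraction,
    Transcriptomics, MultipleComparison
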