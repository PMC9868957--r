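Package: germscore
Title: Predicting Germline Disease Genes from Cancer Somatic Mutation Frequency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a gene's involvement in abnormal germline phenotypes from
    the frequency of its somatic mutations in cancer cohorts, its evolutionary
    age, and genomic/epigenomic covariates. Provides ontology-aware annotation
    propagation with exclusion of a neoplasm subtree, per-gene somatic mutation
    counting from MAF-like tables, feature assembly with standardization and
    PCA decorrelation, univariable and multivariable logistic regression,
    a pluggable classifier bench under nested cross-validation with within-fold
    random oversampling, per-phenotype model training, temporal holdout
    validation, and ontology-aware disease-gene prioritization by geometric-mean
    rank aggregation with a permutation null. A fully parameterised synthetic
    data generator with planted effect sizes makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    ranger,
    glmnet,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
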