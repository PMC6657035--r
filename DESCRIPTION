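Package: ewasrf
Title: Recursive Random-Forest EWAS with Cell-Type Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage epigenome-wide association study (EWAS) pipeline
    for case-control DNA methylation data: split-sample recursive random-forest
    CpG selection with balanced sampling and out-of-bag error tracking,
    medcouple-based adjusted-boxplot outlier trimming on the M-value scale,
    CpG-wise logistic association models (crude and cell-mixture/sex adjusted)
    with Storey q-value FDR control, reference-based cell-type deconvolution
    for adult and cord blood, cross-cohort replication assessment, and a
    DNA-methylation/gene-expression/infant-wheeze follow-up stage. Includes a
    seeded synthetic-cohort generator that emulates the data structure the
    pipeline assumes (Dirichlet cell mixtures with case-shifted eosinophils,
    planted asthma-associated CpGs, anti-correlated expression probes) so that
    every stage can be exercised against a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
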