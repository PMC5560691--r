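Package: UCNR
Title: Unified Censored Normal Regression for qPCR Differential Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential expression analysis for RT-qPCR quantification
    cycle (Cq) data with a unified censored normal regression model.
    Undetermined Cq values are treated as right-censored at the limit of
    detection and a single latent linear model performs normalization and
    group comparison simultaneously, fitted by maximum likelihood with
    per-target variances. Includes modified global mean (MOD) and
    reference-gene normalization, latent mean normalization, the classical
    sequential pipelines (LOD/MNV+1/KNN imputation followed by t or
    Wilcoxon tests) as comparators, generalized Wald tests with
    Benjamini-Hochberg correction and false-coverage-rate adjusted
    fold-change intervals, a censoring-sweep simulation framework, and
    data-driven selection of the limit of detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, tools, Matrix, S4Vectors, MASS, jsonlite
Suggests: testthat (>= 3.0.0), optparse, ggplot2, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, qPCR, DifferentialExpression, Normalization,
    Regression
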