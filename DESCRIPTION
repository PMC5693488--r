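Package: panelcheck
Title: Analytical Verification of Locked Expression-Panel Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical-verification battery applied to locked
    gene-expression panel classifiers run on transbronchial biopsy RNA-seq
    counts: a negative-binomial synthetic count generator with run/lab/replicate
    technical structure, median-of-ratios normalization with a closed-form
    variance-stabilizing transform, a surrogate locked linear classifier on a
    seven-unit score scale, in silico mixture limit-of-detection estimation by
    the 90 percent concordance rule and by spline boundary crossing, interferent
    analyses for blood, genomic DNA and RNA input mass, and reproducibility
    variance components with residual-bootstrap confidence intervals and
    noise-tolerance simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    glmnet,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
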