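Package: mmgsa
Title: Mixed-Model Gene Set Analysis for Case-Control Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained gene set screening for two-group (case versus
    control) expression studies. Each gene set is tested with a linear mixed
    model in which log2 expression is the outcome, disease group is a fixed
    effect, and batch, subject, and eigenvector-derived factor terms (built
    from the within-set gene-gene correlation matrix) are random effects with
    variance components estimated by REML. Screens across a gene set
    collection are adjusted by the Benjamini-Hochberg false discovery rate.
    Includes gene-level follow-up tables with direction-of-change calls,
    threshold-cycle (Ct) based qPCR quantification for confirmation
    experiments, a synthetic data generator matching the model's covariance
    structure, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
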