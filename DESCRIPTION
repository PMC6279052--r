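Package: immunevasion
Title: Immune Evasion Subtyping of Tumors by Sequential Plaid Biclustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subtypes tumor cohorts by immune evasion mechanism from bulk
    gene expression. Fits additive plaid-model biclusters to a log2
    expression matrix and extracts disjoint patient clusters sequentially;
    assesses clustering reproducibility with a Rand-type concordance
    statistic; tests per-cluster differential expression against the
    remaining tumors and against normal tissue (Welch t-test plus log2
    fold-change calls); maps direction calls to six immune evasion
    mechanisms with a declarative rule engine and suggests matched
    immunotherapies; tests cluster association with clinical labels by
    Fisher exact tests; and extracts biomarker genes with expression
    cutoffs from a classification tree. Includes a synthetic cohort
    generator with planted biclusters, mechanism signatures, and biased
    clinical labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
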