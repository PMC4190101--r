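Package: robsig
Title: Robust Gene-Signature Selection for Censored Survival Outcomes by
    Two-Fold Subsampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects robust prognostic feature signatures from
    high-dimensional expression data with right-censored survival
    outcomes.  An inner subsampling loop aggregates and shrinks
    preconditioned-lasso (or lasso-Cox) coefficient vectors into a
    robust model per training set; an outer subsampling loop estimates
    per-feature selection probabilities, held-out concordance, and
    signature stability (Jaccard, Kuncheva, Canberra rank distance,
    rank-penalized Kuncheva).  Includes baseline comparison methods
    (plain lasso-Cox, preconditioned lasso, variance and concordance
    screening with ridge Cox, clinical-only Cox) and a synthetic
    survival-data generator with known sparse linear risk structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
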