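Package: sigrfe
Title: Significance-Weighted SVM Recursive Feature Elimination for
    Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for two-class gene-expression matrices by
    recursive feature elimination with a linear support vector machine,
    where the per-feature ranking criterion combines the SVM weight with
    the two-sided t-test tail probability of the between-class difference.
    Includes the classical weight-only SVM-RFE baseline, bootstrap ensemble
    selection with complete linear rank aggregation, Kuncheva-index
    stability analysis of fixed-size signatures, external cross-validated
    classification error with RBF cost/gamma tuning, rank-position p-value
    profiling, quantile normalization, and a synthetic-data generator with
    planted differential features for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
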