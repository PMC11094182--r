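Package: mutlikeAML
Title: Classifier-Score-Defined TP53 Mutant-Like Subtyping of AML
    Expression Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering a "mutant-like" gene-expression subtype
    in acute myeloid leukemia cohorts. Fits ridge-penalized logistic
    regression of TP53-mutant versus wild-type RNA-seq profiles, derives a
    TP53 mutant-like class from the top decile of wild-type ridge scores,
    trains a complementary wild-type-only model for cross-cohort transfer,
    extracts a compact core gene signature by repeated elastic-net
    selection, and characterizes the derived groups by Kaplan-Meier /
    log-rank survival comparison, drug-sensitivity AUC z-scoring with
    t-test and Benjamini-Hochberg correction, and preranked gene-set
    enrichment with permutation FDR. Includes a negative-binomial
    synthetic-cohort generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    glmnet,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
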