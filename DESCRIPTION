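Package: momic
Title: Multi-Omic Integration and Cross-Species Subtype Classification
    for Mouse Mammary Tumor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrating somatic variant calls, copy
    number, expression, pathway activity, and survival data from mouse
    mammary tumor models and relating them to human breast cancer intrinsic
    subtypes. Provides consensus merging of two-caller SNV and structural
    variant call sets with germline subtraction, copy-number to expression
    correlation (Kendall tau-b and Pearson), single-sample gene set
    enrichment (ssGSEA) scoring, COSMIC-style single base substitution
    signature refitting by constrained forward selection, parametric
    empirical-Bayes batch adjustment, recursive feature elimination with
    cross-validation, a five-learner soft-voting subtype classifier, and
    Kaplan-Meier survival estimation with log-rank comparison. A synthetic
    data module generates every input shape the pipeline consumes so the
    whole analysis is reproducible without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    nnet,
    randomForest,
    xgboost
Suggests:
    jsonlite,
    survival,
    sva,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
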