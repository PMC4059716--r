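Package: triselect
Title: Consensus Gene Selection and Classifier Benchmarking for Two-Group
    Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble feature selection for two-group gene expression
    studies. Three independent rankers -- recursive feature elimination
    driven by a linear support vector machine (SVM-RFE), per-probe ROC
    ranking by (partial) area under the curve, and an all-relevant
    shadow-attribute selector in the style of Boruta built on random
    forests -- are combined by intersecting their top candidate sets after
    an empirical-Bayes moderated-t significance gate. Selected panels are
    benchmarked with six standard classifiers under stratified k-fold
    cross-validation scored by sensitivity, specificity, accuracy and F1.
    Includes a synthetic two-group log-intensity generator with planted
    differential expression for calibration and testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
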