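Package: pepvote
Title: Consensus Feature Selection and Ensemble Voting for Clinical
    Proteomics Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomarker discovery from tabular clinical and mass
    spectrometry peptide-intensity data in binary case-control designs.
    Implements class-conditional mean imputation and min-max scaling,
    a five-method consensus feature selector (Pearson redundancy filter,
    chi-square scoring, recursive feature elimination, random forest
    importance, and L1-penalised logistic regression) with a
    performance-driven consensus-threshold sweep, stratified k-fold
    cross-validation of five classifier families (logistic regression,
    decision tree, k-nearest neighbours, support vector machine, random
    forest), and hard-majority / accuracy-weighted soft ensemble voting.
    A synthetic case-control cohort generator with planted informative
    peptides makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    randomForest,
    rpart,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
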