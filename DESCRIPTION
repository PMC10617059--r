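Package: snfs
Title: Social Network Feature Selection for Biomarker Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid feature selection for high-dimensional two-class
    expression data. Genes are ranked by several feature-selection methods
    (chi-square, information gain, random forest importance, SVM recursive
    feature elimination with square-root batch sizes), the rankings are
    merged, and a candidate subset is carried into a co-occurrence network
    built by repeated k-means on class-mean profiles. Communities are
    detected in the weighted network and biomarkers are selected within each
    community by the corrected degree of domesticity, a ratio of
    within-community to between-community edge counts with an epsilon
    correction that keeps nodes without outside edges finite and comparable.
    A tuned radial-basis-function support vector machine evaluates the
    selected genes on held-out data. Includes a blocked-covariance
    multivariate-normal expression simulator so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
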