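Package: scperf
Title: Predicting Dataset-Specific Performance of Single-Cell RNA-Seq
    Clustering Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the performance of single-cell RNA-seq clustering
    pipelines (filtering, normalization, dimensionality reduction, graph
    clustering) with four unsupervised metrics (Calinski-Harabasz, negated
    Davies-Bouldin, mean silhouette, and a gene-set-enrichment score),
    corrects the cluster-purity metrics for the number of clusters, and
    trains supervised meta-models (random forest, elastic net) that predict
    pipeline performance for unseen datasets from pipeline parameters and
    dataset characteristics (quality-control medians plus probabilistic-PCA
    scores of mean expression).  A negative-binomial synthetic-data
    generator and planted-signal performance tables make the whole study
    reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    Matrix,
    igraph,
    randomForest,
    glmnet,
    scuttle,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea
Config/testthat/edition: 3
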