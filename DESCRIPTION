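Package: progulons
Title: Discovery of Protein Co-Regulation Modules from Perturbation Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects large protein co-regulation modules ("progulons") in a
    protein-by-perturbation log2-ratio matrix. Small, tightly co-regulated
    seed groups are derived by intersecting density-based (OPTICS) clusters
    of a tree-based (treeClust-style) dissimilarity matrix with cohesiveness
    (ClusterONE-style) clusters of the top co-regulation network. Each seed
    is expanded into a module by averaging balanced Random-Forest models
    with leave-one-out cross-validation, quality-control gates on the ROC
    curve and top-scoring proteins, and a Fisher's-exact connectivity
    criterion that selects the minimal score cutoff yielding a significantly
    interconnected module. Also included: exact t-SNE maps of modules,
    annotation enrichment, coordination/contribution statistics for paired
    mRNA/protein panels, Monte-Carlo permutation tests, conservation of
    co-regulation, same-chromosome enrichment, a tiered scoring scheme for
    high-content siRNA screens, and synthetic-data generators for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    data.table,
    rpart,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Clustering, Classification, Network, MachineLearning
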