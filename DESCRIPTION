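Package: adrnet
Title: Network-Based Prediction of Adverse Drug Reaction Liability for Protein Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-centric prediction of adverse drug reaction (ADR)
    liability from protein interaction networks. Computes eight
    network-derived features per protein (diffusion score from seed
    propagation, degree and betweenness centrality, clustering
    coefficient, cluster-dispersion features from diffusion-state-distance
    and Louvain partitions, a Gene Ontology function conservation index,
    and first-quartile distance to a safety-target panel), builds
    per-ADR training sets augmented by DIAMOnD module expansion, trains
    support vector machine, random forest and neural network classifiers
    with grid search and stratified cross-validation, and combines their
    predictions with jury-vote, posterior-weighted consensus and red-flag
    voting rules. Includes a synthetic-fixture generator (scale-free
    interactome with planted ADR modules) so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    Matrix,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
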