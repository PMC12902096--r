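Package: saltadapt
Title: Habitat-Featured Gene Families and Salt-Sensitive Candidate Genes in
    Green Algae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative multi-omics inference chain for identifying
    habitat-featured gene families and salt-sensitive candidate genes in
    green algae. Builds species-by-orthogroup presence-absence matrices,
    classifies saltwater- and freshwater-featured families by a presence
    cutoff with chi-square association statistics and PCA ordination, runs a
    two-stage machine-learning model-combination search with cross-validated
    feature batching, detects cross-species metagene co-expression modules
    via soft-thresholded topological overlap with module-trait association,
    builds transcript-metabolite correlation networks, tests metabolite
    differential abundance, and triages candidate genes by rule-based
    strategies. Includes a synthetic-data generator with planted ground
    truth for recovery benchmarking, and a single-seed pipeline driver with
    a machine-readable run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    e1071,
    rpart,
    class,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
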