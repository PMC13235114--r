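Package: HerbMiner
Title: Mining Core Herb Combinations from Traditional Medicine Prescription Corpora
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying core herb combinations in collections of
    traditional-medicine prescriptions. Provides a prescription-corpus data
    model with name standardization and binary encoding; level-wise Apriori
    frequent-itemset and association-rule mining with support, confidence and
    lift; construction of weighted herb co-occurrence graphs; a two-layer
    graph-convolutional encoder trained under a self-supervised link-prediction
    objective, with silhouette-selected K-means clustering of the embeddings
    and a composite cluster-prioritization score; two-group differential
    analysis via frequency banding and a random-forest classifier with
    out-of-bag error and dual importance measures; consensus extraction of the
    core herb spectrum; threshold-based compound and target screening on
    compound-target bipartite networks; and a synthetic two-group corpus
    generator with planted co-prescription modules for benchmarking every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    cluster,
    randomForest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
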