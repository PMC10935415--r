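Package: znscreen
Title: Property-Based Discovery of Zinc-Binding Fragments and
    Metalloenzyme Inhibitor Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A classification-driven pipeline for characterizing
    zinc-dependent metalloenzyme inhibitors (ZnMIs) and screening
    fragment libraries for candidate zinc-binding fragments (ZnBFs).
    Curates activity-labelled ligand sets from multi-source Ki records
    (log-scale merging, activity classes, MACCS-fingerprint redundancy
    pruning), computes and filters 2D molecular descriptors with an
    emphasis on electronic properties, selects descriptor subsets by
    correlation-based, gain-ratio and wrapper strategies, trains
    interpretable classifiers (naive Bayes, k-nearest neighbours,
    C4.5-style decision trees, rule baselines and attribute-selected
    variants) under repeated stratified cross-validation, and screens
    small-molecule libraries by combining model predictions with
    mean +/- 1.96 sigma electronic-descriptor gates and zinc-binding
    substructure searches.  A synthetic-data generator with planted
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
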