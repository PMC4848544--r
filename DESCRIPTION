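Package: kfsgfs
Title: Feature Subset Selection by Community Modularity of Sample Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filter feature selection for labeled tabular data (for example
    microarray gene-expression matrices) that scores a candidate feature
    subset by the Newman-Girvan community modularity Q of a k-nearest-neighbor
    sample graph built in that subset, with the class labels supplying the
    partition.  Features are selected by greedy forward search (k-FSGFS).
    Includes plug-in conditional mutual information for relevance
    diagnostics, a neighborhood-components-style expected-correct-count
    (ENC) justification, nine-level discretization, a deterministic
    1-nearest-neighbor cross-validation harness with paired one-tailed
    t-tests, a synthetic benchmark generator with group-informative
    (XOR-like), redundant and noise features, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
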