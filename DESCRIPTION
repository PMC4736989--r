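Package: dresmin
Title: Exhaustive Semantic Subgraph Mining of Integrated Drug-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines large typed, directed, attributed multigraphs for
    occurrences of small semantic query subgraphs under a user-set
    semantic-distance threshold, and uses the resulting embeddings to infer
    and rank putative drug-target interactions.  Implements a VF-style
    exhaustive backtracking search with an initial-candidate rule, a
    closed-world (induced-match) pruning rule and semantic thresholding;
    recursive query splitting with join on an overlap node; semantic graph
    pruning; derivation of query subgraphs from shortest semantic paths
    between known drug-target pairs; cumulative query-score ranking of
    inferred interactions; and seeded generators for random semantic graphs
    with planted query instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
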