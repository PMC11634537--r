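Package: discoq
Title: Paralog-Aware Species Tree Estimation by Gene-Tree Decomposition
    and Weighted Quartet Amalgamation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Species tree inference from multi-copy gene family trees in the
    joint presence of gene duplication/loss and incomplete lineage sorting.
    Implements duplication/loss parsimony rooting and tagging of multi-labeled
    gene trees, the DISCO and DISCO-R decompositions into single-copy trees
    (including the regraft-and-contract refinement), speciation-driven quartet
    classification, gene-tree-frequency quartet weighting, exact and
    Fiduccia-Mattheyses-style heuristic solvers for the weighted maximum
    quartet consistency problem, a duplication-loss-coalescence (DLCoal)
    simulator of multi-copy gene trees, and Robinson-Foulds evaluation
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
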