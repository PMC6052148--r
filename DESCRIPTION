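Package: hotrecon
Title: Reconciliation-Based Detection of Horizontal Operon Transfer
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetic tools for detecting horizontal operon
    transfer (HOT) between bacterial lineages: support-aware detection and
    triage of gene-tree versus reference-tree conflicts, error-aware tree
    fixing by rearrangement of weakly supported edges, undated
    duplication-transfer-loss (DTL) maximum-parsimony reconciliation with
    exact co-optimal scenario counting, Dollo loss counting under a
    vertical-inheritance null model, marker selection and
    concerted-evolution tests for operon gene sets, and a synthetic
    operon-evolution simulator with planted transfers and losses for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
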