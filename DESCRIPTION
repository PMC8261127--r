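Package: afcerna
Title: Trait-Linked Co-Expression Modules, ceRNA Networks, and Multiplex
    Random-Walk Prioritization of lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for atrial-tissue expression cohorts that
    builds a signed weighted gene co-expression network, detects modules and
    correlates their eigengenes with atrial-rhythm trait contrasts (AF
    susceptibility and AF persistence), predicts module-specific lncRNA-mRNA
    competing-endogenous-RNA (ceRNA) pairs with a shared-miRNA hypergeometric
    test, prioritizes lncRNAs by random walk with restart on a two-layer
    multiplex network seeded with known disease genes, relates pathway
    activity scores to key lncRNA expression, and classifies rhythm status
    with batch-harmonized random forests validated on an independent cohort.
    A synthetic-data generator with planted ground truth replaces the
    original cohorts so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr,
    yaml
Config/testthat/edition: 3
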