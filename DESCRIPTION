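Package: depcornet
Title: Co-Dependency Networks and Context Associations from CRISPR Fitness Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic dependency correlation networks (DCNs) from
    pan-cancer CRISPR knockout gene-effect matrices: common-essential
    filtering, pairwise-complete Pearson correlation, correlation-cutoff
    calibration against a protein-complex catalog (ROC over observed
    complex pairs versus random pairs), degree-capped network construction,
    and deterministic module calling. The companion association engine
    links per-module dependency scores to molecular context (cancer type,
    binary mutation or signature carriers, continuous chromatin and
    expression features, hallmark signature scores, drug sensitivity)
    with two-sample t-tests and Benjamini-Hochberg FDR control. A
    synthetic-data generator plants correlated modules and context
    couplings so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
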