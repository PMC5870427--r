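Package: tgxprank
Title: Concordance of Toxicogenomic Testing Systems by Pair Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares transcriptomic assay systems that profile the same
    compound panel. Builds directional gene signatures from fold-change
    matrices (top/bottom-k or gene-set-restricted thresholding), scores
    pairwise compound similarity with a direction-aware Dice coefficient,
    quantifies inter-system concordance with a symmetrized rank-based
    ROC-AUC (the PRank score), measures therapeutic-category discrimination
    with within/across-category stability ratios, performs pathway
    over-representation analysis (Fisher's exact test with
    Benjamini-Hochberg correction) with frequency-ranked pathway lists and
    the percentage-of-overlapping-pathways (POP) statistic, and ships a
    seeded multi-system synthetic data generator with controllable
    inter-system signal correlation, category structure and planted
    pathway perturbations so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
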