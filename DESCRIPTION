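Package: intermiR
Title: Integrated mRNA/miRNA Microarray Analysis for Exosomal Biomarker
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering mRNA biomarker candidates
    of a cell substate from paired two-group microarray experiments.
    Implements per-chip percentile-shift normalization with a detection
    floor and optional exosome mass correction, Z-score differential
    expression for mRNA arrays, fold-change plus paired t-test with
    Benjamini-Hochberg correction for cellular and exosomal miRNA
    arrays, target-coverage filtering of predicted miRNA targets with
    direction inversion, intersection of predicted and observed
    differential genes in Entrez ID space, and delta-delta-Ct qPCR
    confirmation. Includes a synthetic-study generator with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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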