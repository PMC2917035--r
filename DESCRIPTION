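Package: pathscore
Title: Dual Molecular-Signature Scoring of PI3K Pathway Activity in ER+ Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives inhibitor-defined transcriptional signatures from two-group
    perturbation expression data (per-gene t tests with Storey q-value FDR
    control), scores individual samples for pathway activity at the mRNA level
    (signature t score on centered log expression) and at the protein level
    (composite reverse-phase protein array score), classifies luminal A versus
    luminal B breast-cancer subtype by mean-centroid correlation (mRNA) or a
    weighted marker score (RPPA), and quantifies score associations with
    estrogen- and progesterone-receptor levels. Includes a synthetic-data
    generator emulating the statistical structure of perturbation experiments
    and ER+ tumor cohorts, plus qPCR delta-delta-Ct and growth-inhibition
    assay arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
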