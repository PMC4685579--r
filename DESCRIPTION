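Package: hydraplast
Title: Epithelial Plasticity Transcriptomics After Interstitial-Lineage Ablation in Hydra
Version: 0.1.0
Authors@R: person("Yann", "Dupont", email = "yann.dupont@posteo.net", role = c("aut", "cre"))
Description: A tested, reusable pipeline for the multi-experiment transcriptomic
    cross-analysis that identifies epithelial "plasticity" genes in Hydra after
    ablation of the interstitial stem-cell lineage. Provides median-of-ratios
    normalization, a negative-binomial Wald differential-expression test with
    Benjamini-Hochberg FDR, classification of axial expression profiles over five
    body regions, ternary cell-type composition from FACS-sorted fraction
    transcriptomes with contamination assessment against unsorted tissue,
    treatment-response signature calling (i-cell loss, gland-cell, plasticity
    candidate) with Venn partitioning across the hydroxyurea, heat-shock and
    colchicine ablation contexts, the RFamide basal-index morphometric statistics,
    and synthetic-data generators for all three experimental designs with ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2
Config/testthat/edition: 3
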