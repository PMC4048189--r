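Package: mitoscreen
Title: Overexpression Screening and Validation Statistics for Mitotic
    Spindle-Checkpoint Genes in Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-dataset transcriptomic overexpression screen for
    candidate therapeutic targets among mitotic spindle-checkpoint genes
    in hepatocellular carcinoma, together with the downstream validation
    statistics used to nominate targets such as the TTK (MPS1) kinase.
    Probe-level log2 expression matrices are median-normalized,
    collapsed to Entrez genes, and screened with a dual gate: a tumor
    sample is called overexpressed when its expression is at least a
    fold threshold above the normal-liver reference, and a gene is
    marked when the calls cover at least a frequency threshold of the
    patient population, aggregated across datasets. Companion modules
    implement qPCR relative quantification (-dCt, ddCt folds with
    a beta-actin reference), paired tumor/adjacent specimen surveys,
    siRNA knockdown QC, and phenotype-assay statistics (CCK-8
    viability, annexin apoptosis fractions, colony counts, caliper
    xenograft volumes). Deterministic synthetic-data generators emulate
    the microarray, qPCR and assay regimes so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
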