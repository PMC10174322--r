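Package: cernet
Title: Competing Endogenous RNA Network Inference from RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for inferring lncRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) networks from multi-layer RNA-seq count data, as
    used in case/control transcriptome studies such as atrial fibrillation
    versus sinus rhythm comparisons. Provides negative-binomial exact-test
    differential expression with median-of-ratios normalization and
    trend-fitted dispersions, miRNA response element (MRE) prediction by
    seed scanning with 5'-weighted local alignment, sign-constrained Pearson
    coexpression screening, MuTaME-style shared-MRE ceRNA scoring, triplet
    network assembly with Cytoscape-compatible export, hypergeometric
    gene-set over-representation analysis, qRT-PCR relative quantification
    (2^-ddCt), and ROC/AUC biomarker evaluation with DeLong confidence
    intervals. A synthetic-data module generates count matrices, transcript
    and miRNA sequences, and annotation with planted ground truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
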