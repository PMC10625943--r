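Package: tissuedom
Title: Integrative Multi-Omics Classification of Tissue-Dominant Genes and Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies genes and proteins measured in two tissues into
    differentially hypomethylated genes (DMGs), differentially expressed
    genes (DEGs) and proteins (DEPs), proteins with different protein/mRNA
    ratios (DRPs), and differentially transcription-factor-bound genes
    (DTGs), together with their direction-consistent composites (DM-DEGs,
    DM-DEPs, DR-DEPs, DT-DEPs). Implements TSS-window methylation summaries
    from whole-genome bisulfite sequencing counts, per-CpG beta-binomial
    differential methylation tests, Otsu thresholding and the Silverman
    bimodality test on promoter methylation ratios, expression-decile and
    sliding-window methylation-expression correlations, negative-binomial
    differential expression, arcsinh variance-stabilizing normalization and
    moderated tests for proteomics, a leave-one-out regression criterion for
    protein/mRNA-ratio outliers, TF-binding-state differential analysis,
    CpG-density clustering, and Fisher-based gene-set enrichment. Ships a
    synthetic paired-tissue multi-omics generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    rlang,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    fgsea
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR
Config/testthat/edition: 3
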