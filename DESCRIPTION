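Package: peakcovar
Title: Promoter Histone-Mark ChIP-seq Enrichment, Covariation and
    Differential Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for promoter-centred analysis of histone-mark (e.g.
    H3K4me3) ChIP-seq experiments with small numbers of biological
    replicates. Reads MACS-style peak files and GENCODE-dialect GTF
    annotation, assigns peaks to promoters (including bidirectional
    promoters) and genomic contexts, and builds peak-by-sample count
    matrices at broad-peak and nucleosome sub-peak resolution.
    Implements median-of-ratios normalization, inter-individual
    variability profiling, extraction of opposing co-varying peak
    clusters, a negative-binomial Wald test for differential enrichment
    with Benjamini-Hochberg FDR control and promoter/input-bias
    post-filters, a 150-bp sliding-window alternative workflow, and a
    qPCR layer (ChIP fold-enrichment QC, geNorm housekeeping stability,
    delta-delta-Ct relative expression with ANOVA/LSD group statistics).
    A fully seeded synthetic-data generator with ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'covariation.R'
    'diffenrich.R'
    'enrichment.R'
    'genomic-io.R'
    'peakcovar-package.R'
    'pipeline.R'
    'qpcr.R'
    'simulate.R'
    'utils.R'
    'windows.R'
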