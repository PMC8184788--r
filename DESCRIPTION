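Package: tomoslam
Title: Spatial Localization and Metabolic-Labeling Analysis of Maternal
    Transcripts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing maternal mRNA localization and fate in early
    embryos. Covers quality control and normalization of serial-section
    (tomo-seq) count matrices with ERCC spike-in based section filtering,
    self-organizing-map clustering of cumulative spatial expression traces
    with multi-replicate vegetal/animal localization calling, per-UMI T-to-C
    classification of metabolically labeled (zygotic) versus unlabeled
    (maternal) transcripts with an analytic false-negative model, cell-type
    fold-change analysis with two-component Gaussian-mixture deconvolution of
    maternal transcript fate, and discriminative k-mer enrichment of 3'UTR
    sequences. Seeded synthetic-data generators with known ground truth are
    provided for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'fate.R'
    'io-misc.R'
    'io-mismatch.R'
    'io-section.R'
    'pipeline.R'
    'sim-slam.R'
    'sim-tomo.R'
    'sim-utr.R'
    'slam.R'
    'som.R'
    'tomo-normalize.R'
    'utils.R'
    'utr-motifs.R'
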