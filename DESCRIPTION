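Package: dualprom
Title: Omics-Driven Promoter Strength Prediction and Dual-Reporter Flow Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bacterial promoter strength from multi-platform omics
    compendia (microarray, RNA-seq, proteomics) by percentile-rank
    classification and cross-platform consensus, resolves candidate genes to
    operon-aware intergenic promoter regions from a GFF3/FASTA annotation,
    and quantifies promoter and ribosome-binding-site strength from
    event-level two-channel flow cytometry using a dual fluorescent reporter
    (EGFP test channel calibrated against constitutive opmCherry).
    Includes seeded simulators for annotations, omics matrices and flow
    events, spillover compensation, tetracycline dose-response calibration,
    and validation reports (prediction-measurement correlation, strength
    class ordering). Ships transcribed reference tables of characterized
    Zymomonas mobilis promoters and synthetic RBS designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
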