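Package: demethr
Title: Differential Methylation, Imprinting and Binding-Peak Analysis for
    Plant DNA-Demethylation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing whole-genome bisulfite sequencing and
    allele-specific expression data from plant DNA-demethylase mutants.
    Implements weighted methylation levels and bisulfite conversion-rate
    estimation, a multi-stage 100-bp-window caller for differentially
    methylated regions (DMRs) in CG/CHG/CHH contexts, intersection of DMR
    sets to define demethylase-sensitive targets, metagene and
    meta-transposon methylation profiles, an endosperm-specificity
    classifier for gene expression, a reciprocal-cross imprinting (MEG/PEG)
    classifier with maternal-contamination filtering, and replicate
    peak-sharing plus peak-methylation comparison for DAP-seq data. A
    synthetic-data module generates all inputs with planted ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
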