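Package: EVAdx
Title: Stepwise Genetic Diagnosis of Enlarged Vestibular Aqueduct from Amplicon Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a stepwise genetic-diagnosis workflow for enlarged
    vestibular aqueduct (EVA) cohorts centred on the SLC26A4 gene: read-depth
    copy-number calling on multiplex-PCR amplicon panels (normalisation to a
    fixed per-sample data amount, cross-sample ratios, state calling,
    segmentation, trio inheritance), exact deletion breakpoint and length
    resolution from long reads with microhomology left-alignment, pseudoexon
    (Alu exonization) splice-consequence prediction with RT-PCR product-size
    simulation, an ACMG/AMP variant-classification engine with ClinGen-style
    PM3 point scaling, and per-patient diagnostic status (M0/M1/M2) with
    cohort-yield reporting. A synthetic-data generator emulates every input
    (depth matrices, long reads, transcripts, pedigrees, variant tables) so
    the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
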