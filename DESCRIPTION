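Package: isodyn
Title: Isoform Dynamics from Long-Read Transcriptome and Proteome Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for studying transcript isoform dynamics
    across a differentiation time course. Collapses long-read exon chains into
    an isoform catalog, classifies isoforms against a reference annotation
    (FSM/ISM/NIC/NNC/fusion), flags reverse-transcription artifacts and applies
    class-specific curation rules; annotates alternative transcription and
    splicing events against the gene's hypothetical pre-mRNA; performs
    differential gene expression, differential transcript usage (dIF) and
    junction-count Psi analyses with regulated-event classification; builds
    positional RNA-binding-protein motif and CLIP-peak maps around cassette
    exons; and detects protein isoform trend changes from unique-peptide
    label-free intensities, including MNAR imputation and NMD prediction. A
    fully seeded synthetic-data generator emulates every input with planted
    ground truth so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    broom,
    dplyr,
    ggplot2,
    GenomicRanges,
    IRanges,
    methods,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
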