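Package: fragtyper
Title: Fragment-Level Genotyping and Fragmentomic Features for Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes cell-free DNA fragments overlapping user-supplied
    small mutations (SNVs, MNVs and indels) starting from an aligned BAM file.
    For every fragment overlapping a mutation the package computes
    fragmentomic features (an indel-aware, optionally soft-clip-preserving
    fragment size, inner distance, reference-derived end motifs, outer
    coordinates and soft-clip counts) and assigns a fragment-level mutation
    status (mutated, wild-type, other, non-informative) from read-level
    sequence-window and CIGAR evidence, with a fragment-level variant allele
    fraction per locus. Mutations in VCF, TSV or colon-string form are
    harmonized to a canonical left-aligned, parsimonious, anchor-based
    representation. A seeded synthetic-data generator produces truth-labelled
    reference/BAM/mutation fixtures emulating cfDNA fragment-size structure,
    planted variants, soft clips and sequencing errors for validation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    VariantAnnotation,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
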