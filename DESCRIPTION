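Package: sigrefit
Title: Mutational Signature Refitting with Bootstrap Stability Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a tumor sample's exposures to known mutational
    signatures from its 96-channel single-base-substitution catalogue by
    constrained quadratic programming, and quantifies the stability of those
    exposures by bootstrap resampling of the catalogue. Builds catalogues
    directly from somatic VCF files against an indexed reference FASTA,
    counts trinucleotide contexts in genomes or capture regions, and
    re-scales catalogues or signature matrices between trinucleotide
    frequency baselines (for example exome versus whole genome). Includes a
    multinomial catalogue simulator for accuracy experiments and
    signature-redundancy diagnostics (pairwise cosine similarity and
    leave-one-out reconstruction stability).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
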