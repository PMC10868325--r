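Package: lrtsim
Title: Modular Simulation of Transcriptomic Long-Read Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates transcriptomic long-read sequencing experiments as a
    chain of independent molecule-transformation modules communicating through
    a tabular Molecule Description Format (MDF). An entry module samples
    molecules from a transcript expression profile (bulk or per-cell, with
    optional random gene-fusion transcripts); core modules model library
    preparation steps (end tagging, polyadenylation, strand flipping, end
    truncation, filtering, merging, PCR amplification with inherited
    substitution errors, single-cell barcode and UMI attachment); an exit
    module realizes molecules against a reference genome and emits FASTQ reads
    with a configurable substitution/indel error model and a per-read truth
    table. Utilities estimate expression profiles and truncation models from
    transcriptome alignments (PAF), a configuration-driven runner composes
    modules into reproducible pipelines, and a fixtures generator builds
    synthetic genomes, annotations, profiles and alignments for fully
    self-contained testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
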