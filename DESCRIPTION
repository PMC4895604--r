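Package: rddkit
Title: Condition-Specific RNA-Editing (RNA/DNA Difference) Prediction from RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate RNA/DNA difference (RDD) sites from RNA-seq
    alignments and classifies them as true RNA-editing events versus systematic
    mis-alignment artefacts. Training data are compiled automatically from the
    input condition itself: positive examples come from curated editing-site
    databases (DARNED/RADAR-style tables), negative examples from a planted-SNV
    mis-alignment simulation (the MES method) that locates error-prone sites
    specific to the genome, read length and aligner in use. Fifteen
    read-alignment-pattern attributes in six categories (read depth, allele
    segregation, mapping quality, read position, base quality, read strand) are
    computed from per-site pileups and fed to a Random Forest. Includes a fully
    synthetic data generator (repeat-bearing genomes, spliced transcripts,
    reads with planted variants, truth-controlled mis-alignments) so every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
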