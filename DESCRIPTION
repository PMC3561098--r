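Package: cybridmt
Title: Comparative Structural Analysis of Cybrid Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares a focal (typically somatic-hybrid, "cybrid") plant
    mitochondrial genome against comparator mitotypes and a chloroplast
    genome.  Provides a seeded local aligner used uniformly across all
    stages, syntenic-region chaining with coverage accounting, large and
    short repeat detection, repeat-mediated recombination modelling
    (subgenomic circles and inverted-repeat isomers, junction
    explanation by flanking repeats), unique-region and
    chloroplast-derived segment calling, gene-level SNP typing
    (transition/transversion, synonymous/non-synonymous), gene
    boundary-shift detection, six-frame ORF finding on circular
    molecules, Kyte-Doolittle transmembrane prediction, screening for
    cytoplasmic-male-sterility candidate ORFs, and a ground-truthed
    synthetic cybrid-genome simulator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
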