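Package: magscope
Title: Reference-Independent Recovery and Refinement of Population-Level
    Genomes from Multi-Sample Metagenomes
Version: 0.1.0
Authors@R:
    person("MAGscope", "Developers", email = "magscope@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying, recovering, and refining population-level
    genomes (metagenome-assembled genomes) from multi-sample metagenomic
    assemblies without reference genomes. Implements two complementary
    workflows: (1) automated co-abundance canopy clustering of gene coverage
    profiles into metagenomic species (MGS), followed by visualization-based
    inspection via k-mer genomic-signature 2D embeddings and polygon
    selection; and (2) targeted recovery guided by taxon-specific marker
    genes ("beacon contigs") grouped by greedy identity clustering. Includes
    essential single-copy-gene completeness and contamination scoring,
    gene-wise GC diagnostics, robust coverage-outlier bin refinement via
    modified Z-scores, and a fully ground-truthed synthetic community
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
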