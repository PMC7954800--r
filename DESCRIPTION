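Package: chrysopan
Title: Ploidy, Nucleotide Composition and Pan-Genome Analysis for
    Chrysophyte Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reusable building blocks for comparative genomics of chrysophyte
    flagellates and similar non-axenic protist cultures: decision rules for
    rescuing unclassified contigs and reads from bacterially contaminated
    assemblies, smudgeplot-style ploidy estimation from heterozygous k-mer
    pairs, assembly and gene-model statistics (N50, gene density, GC content
    partitioned into coding, third-codon-position, intron and intergenic
    fractions), pan- and core-genome set algebra over orthogroup tables with
    majority-rule KEGG annotation, pathway-completeness matrices, and
    trophic-mode group statistics. A synthetic-data generator produces
    polyploid genomes, gene models, contaminant contigs, reads, k-mer coverage
    and orthogroup tables with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
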