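Package: mitocomp
Title: Comparative Analysis of Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes, developed around the stinkhorn fungi
    (Phallales, Basidiomycota). Reads and writes GenBank flat files,
    computes genome composition statistics (GC content, AT/GC strand
    skew), partitions genomes into protein-coding, RNA-coding, intronic
    and intergenic regions, tabulates codon usage under the
    mold/protozoan mitochondrial genetic code, estimates Kimura
    2-parameter distances and Nei-Gojobori (1986) Ka/Ks per gene,
    normalizes and compares circular gene orders including tRNA
    duplication events, and builds concatenated phylogenetic
    supermatrices (codon positions 1+2, with or without rRNAs, and
    amino acids) with partition maps and a neighbor-joining sanity
    tree. A seeded simulator generates Phallales-like annotated
    mitogenomes and sequence sets evolved under K2P or codon models so
    every stage of the pipeline can be exercised with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
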