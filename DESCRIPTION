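Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect mitochondrial
    genomes: per-partition nucleotide composition (AT content, AT-skew,
    GC-skew), codon usage and relative synonymous codon usage (RSCU) under the
    invertebrate mitochondrial genetic code, gene architecture (overlaps,
    intergenic spacers, gene-order rearrangements such as the trnD/trnK
    translocation), tRNA cloverleaf base-pair classification, control-region
    feature discovery (T-stretches, stem-loops, tandem repeats, conserved
    blocks), and phylogenomic supermatrix construction. Includes a synthetic
    mitogenome generator with a ground-truth manifest so every analysis stage
    can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
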