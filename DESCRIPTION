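Package: homeoconv
Title: Detection of Gene Conversion Between Homeologous Genes in
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers gene conversion between homeologous (subgenome) gene
    copies of an allopolyploid from colinear gene quartets.  Detects
    statistically supported colinear (synteny) blocks between gene orders
    by dynamic-programming chaining of protein homology hits, builds a
    reference-anchored multi-genome alignment table, extracts homologous
    gene quartets (two polyploid homeologs plus their diploid/tetraploid
    outgroup orthologs), and calls conversion from aberrant neighbor-joining
    quartet topologies with bootstrap support, assigning donor and acceptor
    copies from cross distances.  Includes Nei-Gojobori Ks/Ka estimation,
    summary tables of conversion rates and donor bias, hypergeometric
    (Fisher exact) GO enrichment, and a synthetic allopolyploid genome
    simulator with known conversion truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
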