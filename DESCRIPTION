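Package: phagenet
Title: Gene-Sharing Network Classification of Bacteriophage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Places bacteriophage genomes in a weighted gene-sharing network
    and decomposes it into taxonomic clusters. Proteins are grouped into
    families from pairwise similarity evidence (BLAST tabular input or a
    built-in scorer), genome pairs are weighted by a hypergeometric
    significance ('Sig') score on shared family content, the network is
    partitioned by a from-scratch Markov clustering (MCL) implementation with
    an inflation sweep selected on intra-cluster homogeneity, and per-node
    cluster memberships quantify genomic mosaicism. Companion tools cover
    network topology (clustering coefficient, betweenness, components),
    reciprocal-best-hit comparative genomics, GC content and direct
    terminal repeat detection, and a synthetic phage-community generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
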