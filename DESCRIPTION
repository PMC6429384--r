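Package: satfam
Title: Life Histories of Satellite DNA Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of satellite DNA (satDNA) family
    evolution from short reads or tandem arrays: all-to-all read-similarity
    clustering with consensus contigs, tandem-repeat detection by wraparound
    dynamic programming with monomer statistics tables, higher-order repeat
    (HOR) unit decomposition and inventory, reconstruction of the conserved
    ancestral monomer fragment from exact shared substrings, alignment-free
    k-mer distance phylogenies rooted on the ancestral monomer, and
    classification of each lineage's satDNA evolutionary mode (concerted
    with mutation/recombination, concerted with HOR formation, or
    non-concerted). Includes a tandem-array evolution simulator (point
    mutation, indels, unequal exchange, gene conversion, HOR formation)
    that provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
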