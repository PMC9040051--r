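Package: cytonuclear
Title: Subgenome Evolutionary Rates and Cytonuclear Incompatibility
    Tests for Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide tests for cytonuclear incompatibility in
    allopolyploids. Infers single-copy orthologous quintets (outgroup, two
    diploid relatives, and the two homoeologous copies of an allotetraploid)
    from gene trees and syntenic ortholog lists, fits branch-specific dN/dS
    under an MG94xHKY codon substitution model by maximum likelihood,
    compares paternal versus maternal subgenome evolutionary rates with
    gene-level and codon-level block bootstraps, classifies genes into
    organelle-targeting and interaction tiers, scores radical amino acid
    autapomorphies at conserved sites, and measures subgenome gene-content
    bias with exact binomial statistics. Includes a codon-model simulator
    that generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
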