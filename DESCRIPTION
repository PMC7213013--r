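Package: haplonet
Title: Haplotype Networks, Consensus Split Systems and Outgroup Placement Rooting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based phylogenetic analysis of multi-marker sequence data
    at shallow evolutionary depths. Reads multiple sequence alignments
    (FASTA, relaxed PHYLIP, NEXUS) and computes per-region diagnostics
    (duplicate sequences, gappyness, distinct alignment patterns); recodes
    length-polymorphic regions into reduced character matrices distinguishing
    single-nucleotide polymorphisms, indels, length-polymorphic tracts and
    linked oligo-nucleotide motifs; builds median-joining and statistical
    parsimony haplotype networks with haplotype-group collapsing; derives
    bootstrap consensus split systems from newick tree sets with an extended
    majority-rule bootstopping criterion; and roots ingroup trees by
    maximum-likelihood placement of outgroup queries, aggregating likelihood
    weight ratios into per-scenario root probabilities. Includes a seeded
    synthetic-data generator (trees, sequences with planted indel, tract and
    motif events, tree-set mixtures, planted query placements) used
    throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
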