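Package: genefam
Title: Gene Family Evolutionary Dynamics: Simulation, Reconciliation,
    Duplication-Mechanism Classification and Codon Branch Models
Version: 0.1.0
Authors@R:
    person("genefam", "developers", email = "genefam@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolutionary dynamics of plant gene
    families that expand by tandem duplication, such as the FLC/MAF-like
    MADS-box genes of Brassicaceae.  Provides a forward simulator of gene
    families evolving along a species tree (tandem, inverted, segmental and
    transposed duplications, triplications, losses, and whole-genome
    duplication/triplication with partial retention), codon sequence
    evolution under a Goldman-Yang style branch model, neighbor-joining
    gene tree estimation with bootstrap support, gene-tree/species-tree
    reconciliation by LCA mapping with duplication and loss inference,
    classification of duplication mechanisms from genomic coordinates,
    maximum-likelihood fitting of one-ratio and branch codon models
    (dN/dS per branch class) and the associated likelihood-ratio test,
    plus readers and writers for FASTA, newick and tabular locus formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
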