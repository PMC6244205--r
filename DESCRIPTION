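Package: ltpscan
Title: Genome-Wide Identification and Evolutionary Analysis of Plant
    Non-Specific Lipid Transfer Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining plant genomes for non-specific lipid transfer
    proteins (nsLTPs) and characterising the resulting gene family.
    Implements eight-cysteine-motif (8CM) pattern scanning over proteins and
    six-frame translations, type classification (1, 2, C, D, G) from GPI
    status and intron architecture, mature-protein derivation and
    physicochemical profiling (molecular weight, isoelectric point), tandem
    duplication detection under an 80/80 homology rule, Nei-Gojobori (1986)
    Ka/Ks estimation with Jukes-Cantor correction and duplication dating,
    UPGMA phylogenies with Newick export, FPKM expression clustering with
    anther-enrichment calling, and promoter motif enrichment (rank-sum test
    of known boxes and DREME-style de novo k-mer discovery). A synthetic
    genome generator with recorded ground truth makes the whole pipeline
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
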