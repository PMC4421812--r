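Package: kelpscan
Title: Selective-Sweep Scans and Comparative Genomics for Kelp Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of the population-genomic and
    comparative-genomic analyses used in brown-algal (kelp) genome studies:
    sliding-window nucleotide diversity, Watterson's theta and Tajima's D with
    empirical-tail selective-sweep region calling; neighbour-joining trees with
    bootstrap support from homozygous-SNP p-distances; Dollo parsimony
    gain/loss reconstruction of gene families; Jukes-Cantor-corrected
    transposable-element age distributions; Nei-Gojobori (1986) Ka/Ks;
    Fisher-exact gene-family expansion tests with multiple-testing correction;
    tandem-duplication cluster detection; and a GC/ORF-density contamination
    filter for assembled contigs. A seeded synthetic-data generator (Kingman
    coalescent with a two-population bottleneck model, Dollo-compatible family
    evolution, decayed repeat copies, codon-pair divergence, and mixed
    host/bacterial contigs) provides inputs with recorded ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
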