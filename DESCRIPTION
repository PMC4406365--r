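Package: teopop
Title: Population Genetics of the Hopscotch Insertion at the Maize
    Domestication Locus tb1 in Teosinte
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing natural variation at the teosinte
    branched1 (tb1) domestication locus in wild Zea mays (teosinte).
    Implements co-dominant PCR band-pattern genotyping of the Hopscotch
    retrotransposon insertion, allele-frequency and Hardy-Weinberg
    analysis, hierarchical Weir-Cockerham F-statistics, standard sequence
    diversity statistics (Watterson's theta, pairwise nucleotide
    diversity, Tajima's D) with a neutral-coalescent simulation null,
    linkage-disequilibrium r-squared and fixed-window haplotype-block
    recoding, neighbor-joining trees with bootstrap support, and
    repeated-measures genotype-phenotype association for tillering.
    Includes seeded synthetic-data generators for every input class so
    the full analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
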