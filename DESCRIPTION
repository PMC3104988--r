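Package: breedmode
Title: Inference of Reproductive Mode in Cyclically and Obligately
    Parthenogenetic Populations from Multilocus Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to infer the breeding system (obligate parthenogenesis,
    cyclic parthenogenesis, or a mixed/uncertain mode) of diploid
    populations from codominant multilocus genotypes and mitochondrial
    sequence data.  Implements multilocus genotype (MLMG) partitioning and
    clonality statistics (probability of identity, P_sex, genotypic
    richness, genotypic diversity ratio), Weir-Cockerham inbreeding
    coefficients with permutation tests, Markov-chain exact score tests of
    Hardy-Weinberg equilibrium, the standardized index of association
    (r_bar_d) with and without clone correction, individual-level
    ordination (binary allele coding, Nei/Dice distance, principal
    coordinate analysis, cascaded K-means with the Calinski-Harabasz
    criterion), Cavalli-Sforza chord distances, mtDNA haplotype diversity
    statistics, in-silico restriction digestion, and seeded synthetic
    population generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
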