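Package: introgressr
Title: Introgression Inference from Gene Trees, Genotypes and Linkage Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies phylogenetic discordance and introgression in small
    species radiations. Implements rooted gene-tree topology weighting with
    clade aggregation and along-genome smoothing, Patterson's D and the
    five-taxon D_FOIL statistics with block-jackknife significance, the
    three-taxon D2 divergence test for the direction of introgression,
    per-region nucleotide diversity and divergence, and recombination-rate
    landscapes estimated from linkage maps. A multispecies network
    coalescent simulator with configurable introgression events and
    recombination-coupled gene flow provides ground-truthed data for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    vcfR,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
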