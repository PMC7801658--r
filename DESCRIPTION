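Package: popref
Title: Population-Consensus Reference Genome Construction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building a population-specific consensus reference
    genome from multiple haploid de novo assemblies. Variants are called from
    whole-assembly pairwise alignments against a backbone assembly, normalized,
    and put to a majority vote; major alleles are substituted into the backbone
    with full coordinate tracking. Scaffolds are anchored to chromosomes with
    genetic and radiation-hybrid marker maps via in-silico STS PCR, liftover
    chain files are generated for annotation transfer, and the consensus is
    evaluated with structural-variant depth statistics and an unfolded site
    frequency spectrum against a population allele-frequency panel. Includes a
    seeded synthetic-data generator producing ground-truthed fixtures for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
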