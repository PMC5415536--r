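Package: tetraqst
Title: Tetraploid Genotype Calling and QST-FST Analysis for Half-Sib Common-Garden Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for latitudinal trait variation in the
    autotetraploid grass Arrhenatherum elatius and similar half-sib
    common-garden studies. Calls tetraploid codominant genotypes from
    biallelic genotyping-by-sequencing read counts by binomial maximum
    likelihood with likelihood-ratio-test confidence, computes
    sample-size-corrected gene diversity and Weir-Cockerham FST on allele
    copies, estimates variance components of the nested half-sib design by
    Markov chain Monte Carlo (heritability, evolvability, QST), tests
    quantitative differentiation against the simulated neutral QST
    distribution of Whitlock and Guillaume, and relates family-level
    plasticity indices to fitness. A synthetic-data generator reproduces
    the study design (8 populations x 5 seed families x 15 offspring under
    3 winter treatments) with known truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
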