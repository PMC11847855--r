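Package: polybreed
Title: Stochastic Simulation of Polyploid Breeding Programs with
    Multi-Allelic QTL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of plant and animal
    breeding programs at arbitrary even ploidy. Genotypic values are built
    from generalized multi-allelic models for additive, digenic dominance
    and two-locus epistatic (additive x additive, additive-dominance,
    dominance x dominance) effects, with functional effect sizes sampled,
    centered and rescaled against a founder population. Founder genomes
    with linkage disequilibrium are generated by Fisher-Wright simulation
    with recombination under bivalent chromosome pairing; breeding schemes
    combine pseudo-random crossing, genomic evaluation with VanRaden-type
    additive and digenic dominance relationship matrices, AI-REML variance
    component estimation, GBLUP prediction and truncation selection, and
    report prediction accuracy and rates of genetic gain over replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
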