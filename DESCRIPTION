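Package: islandGS
Title: Stochastic Simulation of Recurrent Genomic Selection with Island-Model
    Population Structure in Autogamous Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stochastic breeding-program simulator for autogamous (selfing)
    crops such as rice. Simulates meiosis over a genetic map, bi-parental
    crossing, and single-seed-descent inbreeding; generates synthetic founder
    panels of fully inbred lines with ancestry-driven cluster structure;
    simulates additive QTL architectures with geometric-series heritability
    weights; fits G-BLUP genomic prediction models by REML on a realized
    additive relationship matrix; and runs recurrent genomic selection under
    three population topologies (discrete per-cross families, one bulked
    admixed population, and an island model of subpopulations connected by
    ring migration), with truncation selection, single round-robin mating,
    optional mid-program model updating, and trajectory summary statistics
    (attained genotypic value, genetic variance, prediction accuracy,
    heterozygosity, locus fixation, family selection bias).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
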