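Package: breedscan
Title: Population Genomics of Livestock Breeds from SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Conservation-genomics toolkit for SNP-array genotype panels of
    livestock breeds. Reads and writes PLINK text (PED/MAP) and binary
    (BED/BIM/FAM) genotype files, applies autosome/position variant filters,
    and provides breed-differentiation analyses (allele frequencies,
    Patterson-scaled PCA, pairwise weighted Weir-Cockerham F_ST), genomic
    inbreeding (heterozygosity-based F, sliding-window runs of homozygosity,
    F_ROH, length-class summaries, nonparametric group comparisons),
    LD-based historical effective population size trajectories, and a
    composite selection-signal scan (per-SNP F_ST, allele-frequency
    difference, cross-population extended haplotype homozygosity, rank-probit
    combination, window smoothing, and peak calling with candidate-gene
    lookup). Includes two seeded simulators - a Balding-Nichols multi-breed
    genotype sampler and a forward Wright-Fisher simulator with
    recombination, mating plans and selective sweeps - so every stage is
    testable against known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
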