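Package: volescape
Title: Landscape Genetics of Fossorial Water Vole Demes in Bocage Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic and landscape-genetic analysis of diploid
    microsatellite genotypes sampled from discrete demes in a fine-grained
    agricultural mosaic. Reads Genepop genotype files and ESRI ASCII land-cover
    grids; computes diversity statistics (allelic richness by hypergeometric
    rarefaction, Nei's unbiased heterozygosity, Weir-Cockerham F-statistics with
    permutation and bootstrap uncertainty), exact Hardy-Weinberg and genotypic
    linkage-disequilibrium tests with a disequilibrium-based locus filter,
    graph-based least-cost paths over categorical resistance surfaces with
    effective, resistance and lens-buffer habitat-suitability distances,
    model-based Gibbs clustering with Delta-K selection, three-level AMOVA,
    Mantel and partial Mantel causal modelling with reduced-major-axis
    regression, multilocus spatial autocorrelation in distance classes, and
    first-generation migrant detection by home-deme likelihood. Includes a
    forward Wright-Fisher simulator on synthetic category landscapes so the
    whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vegan, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
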