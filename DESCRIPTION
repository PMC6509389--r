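Package: ibrsamp
Title: Sampling-Scheme Evaluation for Landscape Genetics Under Isolation by
    Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare individual-, population-, and
    proportion-available sampling schemes (ISS, PSS, PASS) in landscape
    genetics. Computes interindividual allele-sharing distances for diploid
    microsatellite genotypes, circuit-theory effective resistance between
    sites on raster resistance surfaces, and fits maximum-likelihood
    population-effects (MLPE) mixed models of pairwise genetic distance on
    resistance predictors, ranked by AICc and BIC under ML and REML.
    Includes bootstrap resampling of individuals per site with
    competitive-model counting and convergence analysis, population-genetic
    summaries (unbiased heterozygosity, rarefied allelic richness, private
    alleles, Monte Carlo Hardy-Weinberg and linkage-disequilibrium tests),
    GenePop and CSV genotype input/output, ESRI ASCII raster input/output,
    and a forward Wright-Fisher stepping-stone simulator that generates
    landscapes, sites, and genotypes with known isolation-by-resistance
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
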