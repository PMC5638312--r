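Package: refugia
Title: Microsatellite Population Genetics and Niche-Model Hindcasting for
    Glacial Refugia Inference
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-track analysis pipeline for locating Pleistocene glacial
    refugia of long-lived plants from germplasm collections. One track
    computes codominant-microsatellite diversity and differentiation
    statistics (expected/observed heterozygosity, rarefied allelic and
    private allelic richness, Nei's gene-diversity decomposition, distance
    AMOVA with permutation tests, pairwise FST, contingency chi-square),
    distance-based clustering (shared-allele and Nei-Li distances, neighbor
    joining with locus-bootstrap support, genotype PCA) and Bayesian
    admixture clustering with Evanno delta-K model choice. The other track
    fits maximum-entropy species distribution models with l1-regularized
    feature expansions, spatial occurrence thinning and kernel-density
    sampling-bias grids, block cross-validation tuning over feature-class
    and regularization grids with AICc selection, Schoener's D niche
    overlap, and projection onto alternative (paleo) climate layers.
    Seed-deterministic synthetic-data generators make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
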