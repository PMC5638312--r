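test_that("fixation index reproduces published locus arithmetic", {
  # He/Ho pairs from the shipped locus-statistics table
  tab <- read.table(system.file("extdata", "walnut_locus_stats.tsv",
                                package = "refugia"), header = TRUE, sep = "\t")
  per_locus <- tab[tab$locus != "Mean", ]
  expect_equal(round(fixation_index(0.836, 0.326), 3), 0.610)
  expect_equal(round(fixation_index(0.810, 0.605), 3), 0.253)
  # identity holds across the whole printed table at printed precision
  expect_true(all(abs(fixation_index(per_locus$He, per_locus$Ho) -
                        per_locus$F) < 0.0065))
})

test_that("locus_diversity computes He, Ho and both mean-F conventions", {
  gt <- toy_gt(list(list(c(1, 2)), list(c(1, 2)), list(c(1, 1)), list(c(2, 2))))
  ld <- locus_diversity(gt)
  expect_equal(ld$He, 0.5)                     # two equifrequent alleles
  expect_equal(ld$Ho, 0.5)
  expect_equal(ld$F, 0)
  m <- attr(ld, "means")
  expect_named(m, c("n", "A", "He", "Ho", "F", "F_from_means"))
  # monomorphic locus: He = 0 and F undefined, not 0
  gt0 <- toy_gt(list(list(c(1, 1)), list(c(1, 1))))
  expect_true(is.na(locus_diversity(gt0)$F))
})

test_that("rarefied richness matches hand and enumeration oracles", {
  # counts {9,1}, N = 10, g = 2: 1 - C(1,2)/C(10,2) + 1 - C(9,2)/C(10,2) = 1.2
  gt <- toy_gt(lapply(1:5, function(i) list(if (i < 5) c(1, 1) else c(1, 2))))
  ac <- allele_counts(gt)
  expect_equal(rarefied_allelic_richness(ac, 2)[1, 1], 1.2)
  # g = N returns the observed allele count exactly
  expect_equal(rarefied_allelic_richness(ac, 10)[1, 1], 2)
  # exhaustive oracle on small count vectors
  for (cts in list(c(3, 2, 1), c(4, 1, 1), c(2, 2, 2))) {
    g <- 3
    gt2 <- toy_gt(lapply(seq_len(sum(cts) / 2), function(i) {
      copies <- rep(seq_along(cts), cts)
      list(c(copies[2 * i - 1], copies[2 * i]))
    }))
    ac2 <- allele_counts(gt2)
    expect_equal(rarefied_allelic_richness(ac2, g)[1, 1], enum_ar(cts, g))
  }
  # monotone in g, and Ar(2) <= 2
  ar_g <- vapply(2:10, function(g) rarefied_allelic_richness(ac, g)[1, 1], 0)
  expect_true(all(diff(ar_g) >= -1e-12))
  expect_lte(ar_g[1], 2)
  expect_error(rarefied_allelic_richness(ac, 11), "exceeds")
  expect_error(rarefied_allelic_richness(ac, 1), ">= 2")
})

test_that("rarefied richness agrees with a Monte-Carlo subsampling oracle", {
  cts <- c(12, 5, 2, 1)
  gt <- toy_gt(lapply(seq_len(sum(cts) / 2), function(i) {
    copies <- rep(seq_along(cts), cts)
    list(c(copies[2 * i - 1], copies[2 * i]))
  }))
  g <- 6
  ar <- rarefied_allelic_richness(allele_counts(gt), g)[1, 1]
  set.seed(42)
  copies <- rep(seq_along(cts), cts)
  draws <- replicate(1e5, length(unique(copies[sample.int(length(copies), g)])))
  expect_lt(abs(mean(draws) - ar), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("private rarefied richness follows its closed form and oracle", {
  two_group_gt <- function(c1, c2) {
    mk <- function(cts) {
      copies <- rep(seq_along(cts), cts)
      lapply(seq_len(sum(cts) / 2), function(i) list(c(copies[2 * i - 1], copies[2 * i])))
    }
    calls <- c(mk(c1), mk(c2))
    toy_gt(calls, group = rep(c("A", "B"), c(sum(c1) / 2, sum(c2) / 2)))
  }
  # allele only in focal group contributes exactly its Q
  gt <- two_group_gt(c(2, 2, 0), c(2, 0, 2))   # allele 2 private to A, 3 to B
  ac <- allele_counts(gt)
  g <- 2
  par <- private_rarefied_richness(ac, g)
  q2 <- 1 - exp(lchoose(2, 2) - lchoose(4, 2)) # Q of a 2-copy allele in N=4
  q_shared <- 1 - exp(lchoose(2, 2) - lchoose(4, 2))
  expect_equal(par["A", 1], q2 * (1 - q_shared) + q2)
  # identical groups: every allele contributes Q * (1 - Q)
  gt2 <- two_group_gt(c(2, 2), c(2, 2))
  par2 <- private_rarefied_richness(allele_counts(gt2), 2)
  expect_equal(par2["A", 1], par2["B", 1])
  expect_equal(par2["A", 1], 2 * q2 * (1 - q2))
  # exhaustive enumeration over all subsample pairs
  for (cfg in list(list(c(3, 1), c(2, 2)), list(c(2, 2), c(4, 0)))) {
    gt3 <- two_group_gt(cfg[[1]], cfg[[2]])
    par3 <- private_rarefied_richness(allele_counts(gt3), 2)
    expect_equal(par3["A", 1], enum_par(cfg[[1]], cfg[[2]], 2))
    expect_equal(par3["B", 1], enum_par(cfg[[2]], cfg[[1]], 2))
  }
})

test_that("PAr never exceeds Ar at the same g", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(12, 10, 14),
                                              n_loci = 6, n_alleles = 6,
                                              F = 0.2, seed = 5))
  ac <- allele_counts(sim$gt)
  g <- default_rarefaction_g(ac)
  expect_true(all(private_rarefied_richness(ac, g) <=
                    rarefied_allelic_richness(ac, g) + 1e-12))
})

test_that("private allele inventory counts alleles in exactly one group", {
  gt <- toy_gt(list(list(c(1, 2)), list(c(3, 4))), group = c("A", "B"))
  inv <- private_allele_inventory(allele_counts(gt))
  expect_equal(unname(inv$n), c(2L, 2L), ignore_attr = TRUE)  # disjoint: all private
  gt2 <- toy_gt(list(list(c(1, 2)), list(c(1, 3))), group = c("A", "B"))
  inv2 <- private_allele_inventory(allele_counts(gt2))
  expect_false("L1.1" %in% unlist(inv2$alleles))  # shared allele not private
  expect_equal(attr(inv2$n, "total"), 2L)
})

test_that("group_diversity assembles a coherent per-group table", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(15, 15),
                                              n_loci = 5, n_alleles = 6,
                                              F = 0.15, seed = 3))
  gd <- group_diversity(sim$gt)
  expect_equal(gd$group[nrow(gd)], "Mean")
  per <- gd[gd$group != "Mean", ]
  expect_true(all(per$Ar <= per$A + 1e-12))
  expect_true(all(per$PAr <= per$Ar + 1e-12))
  expect_equal(gd$He[nrow(gd)], mean(per$He))
})
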