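test_that("shared-allele distance matches hand counts", {
  gt <- toy_gt(list(list(c(1, 2)), list(c(1, 3))))
  expect_equal(shared_allele_distance(gt)[1, 2], 0.5)   # (A,B) vs (A,C)
  gt2 <- toy_gt(list(list(c(1, 2), c(3, 3)), list(c(1, 2), c(3, 3))))
  expect_equal(shared_allele_distance(gt2)[1, 2], 0)    # identical
  gt3 <- toy_gt(list(list(c(1, 2)), list(c(3, 4))))
  expect_equal(shared_allele_distance(gt3)[1, 2], 1)    # disjoint
  # missing loci are excluded pairwise
  gt4 <- toy_gt(list(list(c(1, 1), c(5, 5)), list(c(1, 1), NA)))
  d4 <- shared_allele_distance(gt4)
  expect_equal(d4[1, 2], 0)
  expect_equal(attr(d4, "n_loci")[1, 2], 1L)
})

test_that("Nei-Li distance matches its closed form", {
  bm <- rbind(x = c(1, 1, 1, 0, 0, 0, 0, 0),
              y = c(1, 1, 0, 1, 1, 1, 0, 0))
  expect_equal(nei_li_distance(bm)["x", "y"], 0.5)      # nx=3, ny=5, nxy=2
  expect_equal(nei_li_distance(rbind(a = c(1, 0), b = c(1, 0)))["a", "b"], 0)
  expect_equal(nei_li_distance(rbind(a = c(1, 0), b = c(0, 1)))["a", "b"], 1)
  expect_error(nei_li_distance(rbind(a = c(0, 0), b = c(1, 0))), "no allele")
})

test_that("distances are symmetric, zero-diagonal and metric-ish on toys", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(10, 10),
                                              n_loci = 8, n_alleles = 6,
                                              F = 0.2, seed = 21))
  d <- shared_allele_distance(sim$gt)
  expect_true(isSymmetric(unclass(d)[seq_len(nrow(d)), ]))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  b <- nei_li_distance(binary_presence_matrix(sim$gt))
  expect_true(isSymmetric(b))
  expect_true(all(diag(b) == 0))
  expect_true(all(b >= 0 & b <= 1))
  # triangle violations are logged, not fatal: Dice-type dissimilarities are
  # not guaranteed metrics
  nviol <- 0L
  n <- nrow(b)
  for (k in seq_len(n)) nviol <- nviol + sum(b > outer(b[, k], b[k, ], "+") + 1e-12)
  if (nviol > 0) message("Nei-Li triangle violations on fixture: ", nviol)
  expect_lt(nviol / (n^3), 0.05)
})

test_that("NJ recovers additive trees exactly", {
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$edge.length), c(2, 3, 3, 4, 4))
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[letters[1:4], letters[1:4]]),
               unname(D))
  # random additive trees up to 8 taxa
  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(length(true$edge.length), 0.1, 2)
    D2 <- as.matrix(ape::cophenetic.phylo(true))
    rec <- neighbor_joining(D2)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), rec)), 0)
    expect_equal(sum(rec$edge.length), sum(true$edge.length))
  }
})

test_that("3-taxon NJ gives the closed-form star tree", {
  D <- matrix(2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  expect_equal(sort(unique(round(tr$edge.length, 10))), 1)
})

test_that("NJ is invariant to taxon order", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(6, 6),
                                              n_loci = 10, n_alleles = 6,
                                              F = 0.3, seed = 14))
  d <- shared_allele_distance(sim$gt)
  t1 <- neighbor_joining(d)
  perm <- sample(nrow(d))
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("locus bootstrap gives high support for a clean split", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(6, 6),
                                              n_loci = 12, n_alleles = 4,
                                              F = 0.85, seed = 31))
  tr <- bootstrap_support(sim$gt, n_reps = 60, seed = 7)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100))
  grp_tips <- sim$gt$id[sim$gt$group == "G1"]
  # find the edge splitting the two simulated clusters and check its support
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  split_support <- NA_real_
  for (i in seq_along(parts)) {
    clade <- labs[parts[[i]]]
    if (setequal(clade, grp_tips) || setequal(clade, setdiff(labs, grp_tips)))
      split_support <- tr$node.label[i]
  }
  expect_gte(split_support, 95)
  # seed determinism
  tr2 <- bootstrap_support(sim$gt, n_reps = 60, seed = 7)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("genotype PCA has the expected geometry", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(8, 8),
                                              n_loci = 6, n_alleles = 5,
                                              F = 0.3, seed = 17))
  gt <- sim$gt
  dup <- genotype_table(rbind(gt$a1, gt$a1[1, , drop = FALSE]),
                        rbind(gt$a2, gt$a2[1, , drop = FALSE]),
                        id = c(gt$id, "copy"), group = c(gt$group, gt$group[1]),
                        loci = gt$loci)
  pc <- pca_genotypes(dosage_matrix(dup))
  expect_equal(unname(pc$scores[1, ]), unname(pc$scores[nrow(pc$scores), ]))
  expect_true(all(diff(pc$var_frac) <= 1e-12))
  expect_lte(sum(pc$var_frac), 1 + 1e-12)
  # 2D toy with known covariance eigenvalues
  set.seed(3)
  x <- rnorm(400); y <- 0.5 * x + rnorm(400, sd = 0.1)
  pc2 <- prcomp(cbind(x, y))
  ev <- eigen(stats::cov(cbind(x, y)))$values
  expect_equal(pc2$sdev^2, ev)
})
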