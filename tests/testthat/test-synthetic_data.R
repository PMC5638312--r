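test_that("genotype simulator is seed-deterministic and obeys its spec", {
  spec <- genotype_sim_spec(group_sizes = c(10, 10), n_loci = 4, n_alleles = 5,
                            F = 0.2, missing_rate = 0.1, seed = 3)
  s1 <- simulate_genotypes(spec)
  s2 <- simulate_genotypes(spec)
  expect_identical(s1$gt$a1, s2$gt$a1)
  expect_error(genotype_sim_spec(F = 0), "strictly inside")
  expect_error(genotype_sim_spec(F = 1), "strictly inside")
  # missing rate roughly honored
  big <- simulate_genotypes(genotype_sim_spec(group_sizes = c(100, 100),
                                              n_loci = 10, missing_rate = 0.2,
                                              seed = 5))
  expect_lt(abs(mean(is.na(big$gt$a1)) - 0.2), 0.02)
})

test_that("near-zero F produces near-zero differentiation", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(200, 200),
                                              n_loci = 10, n_alleles = 8,
                                              F = 0.001, seed = 6))
  nd <- nei_decomposition(allele_counts(sim$gt))
  expect_lt(nd$GGT[nd$locus == "Mean"], 0.01)
})

test_that("private-allele injection shows up in the inventory", {
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(20, 20),
                                              n_loci = 10, n_alleles = 4,
                                              F = 0.2, private_rate = 0.8,
                                              seed = 7))
  expect_gt(nrow(sim$truth$injected), 0)
  inv <- private_allele_inventory(allele_counts(sim$gt))
  # every injected allele code is above the ancestral pool, hence private
  expect_gte(attr(inv$n, "total"), nrow(unique(sim$truth$injected[, c("group", "locus")])))
})

test_that("landscape simulator produces the stated suitability surface", {
  spec <- landscape_sim_spec(n_row = 25, n_col = 25, n_cov = 2, coefs = c(0, 0),
                             seed = 4)
  land <- simulate_landscape(spec)
  expect_equal(max(land$suitability$values), min(land$suitability$values))
  expect_equal(sum(land$suitability$values), 1)
  land2 <- simulate_landscape(landscape_sim_spec(n_row = 25, n_col = 25,
                                                 n_cov = 2, coefs = c(1, -1),
                                                 seed = 4))
  # suitability is exp(coefs . covariates), normalized
  lin <- land2$stack$cov1$values - land2$stack$cov2$values
  expect_equal(land2$suitability$values, exp(lin) / sum(exp(lin)))
  expect_identical(simulate_landscape(spec)$stack$cov1$values,
                   land$stack$cov1$values)        # seed-deterministic
})

test_that("longer smoothing kernels raise spatial autocorrelation", {
  lag1_cor <- function(sigma) {
    land <- simulate_landscape(landscape_sim_spec(n_row = 50, n_col = 50,
                                                  n_cov = 1, coefs = 1,
                                                  autocorr_cells = sigma,
                                                  seed = 11))
    M <- land$stack$cov1$values
    cor(as.vector(M[, -1]), as.vector(M[, -ncol(M)]))
  }
  expect_gt(lag1_cor(6), lag1_cor(1))
  expect_gt(lag1_cor(1), lag1_cor(0))
})

test_that("occurrence sampling follows suitability-times-bias weights", {
  flat <- grid_raster(matrix(1 / 25, 5, 5), 0, 0, 1)
  occ <- sample_occurrences(flat, 1e4, seed = 8)
  cells <- cell_of(flat, occ$lon, occ$lat)
  counts <- table(factor(paste(cells[, 1], cells[, 2]),
                         levels = outer(1:5, 1:5, paste)[1:25]))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  # multiplicative bias concentrates samples in the biased quadrant
  bias <- grid_raster(matrix(c(rep(9, 10), rep(1, 15)), 5, 5), 0, 0, 1)
  occ_b <- sample_occurrences(flat, 2000, bias = bias, seed = 9)
  cells_b <- cell_of(flat, occ_b$lon, occ_b$lat)
  frac <- mean(cells_b[, "col"] <= 2)
  expect_gt(frac, 0.6)                          # expected 9*10/(9*10+15) = 0.857
  # n = 1 lands inside a valid cell
  one <- sample_occurrences(flat, 1, seed = 10)
  expect_equal(nrow(one), 1L)
  expect_false(anyNA(cell_of(flat, one$lon, one$lat)))
})

test_that("climate shifting is affine, shape-preserving, and neutral for
           unclamped log-linear models", {
  land <- simulate_landscape(landscape_sim_spec(n_row = 20, n_col = 20,
                                                n_cov = 1, coefs = 1.2, seed = 12))
  st0 <- shift_climate(land$stack, offsets = 0)
  expect_equal(st0$cov1$values, land$stack$cov1$values)
  st <- shift_climate(land$stack, offsets = 0.5, scales = 2)
  expect_equal(st$cov1$values, land$stack$cov1$values * 2 + 0.5)
  expect_equal(dim(st$cov1$values), dim(land$stack$cov1$values))
  # a uniform shift re-ranks nothing for a single-covariate linear model
  occ <- sample_occurrences(land$suitability, 60, seed = 13)
  ev <- land_env(land, occ)
  fit <- fit_maxent(ev$occ, ev$grid, classes = "L", rm = 0.5)
  pr0 <- project_model(fit, land$stack, clamp = FALSE)
  pr1 <- project_model(fit, shift_climate(land$stack, offsets = 0.3),
                       clamp = FALSE)
  expect_equal(pr1$values, pr0$values, tolerance = 1e-10)
})

test_that("fixture writer emits consumable plain-text artifacts", {
  dir <- withr::local_tempdir()
  sim <- simulate_genotypes(genotype_sim_spec(group_sizes = c(5, 5), n_loci = 3,
                                              seed = 2))
  land <- simulate_landscape(landscape_sim_spec(n_row = 8, n_col = 8, n_cov = 2,
                                                coefs = c(1, 0), seed = 2))
  occ <- sample_occurrences(land$suitability, 20, seed = 2)
  paths <- write_sim_fixtures(dir, gt = sim$gt, occ = occ, stack = land$stack)
  gt2 <- read_genotype_table(file.path(dir, "genotypes.csv"))
  expect_identical(gt2$a1, sim$gt$a1)
  r2 <- read_ascii_grid(file.path(dir, "cov1.asc"))
  expect_equal(r2$values, land$stack$cov1$values, tolerance = 1e-12)
})
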