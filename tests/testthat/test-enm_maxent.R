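make_env <- function(n, k = 2, seed = 1, mean = 0) {
  set.seed(seed)
  matrix(rnorm(n * k, mean = mean), n, k,
         dimnames = list(NULL, paste0("v", seq_len(k))))
}

test_that("feature expansion follows the scaled formulas", {
  env <- matrix(c(0, 10, 5), 3, 1, dimnames = list(NULL, "v"))
  fx <- feature_expansion(env, c("L", "Q", "H", "T"), n_knots = 3)
  F <- expand_features(matrix(5, 1, 1, dimnames = list(NULL, "v")), fx)
  expect_equal(unname(F[1, "L.v"]), 0.5)
  expect_equal(unname(F[1, "Q.v"]), 0.25)
  # forward hinge with knot at 0.5, input 0.75 -> half of remaining range
  fx$knots <- c(0.25, 0.5, 0.75)
  F2 <- expand_features(matrix(7.5, 1, 1, dimnames = list(NULL, "v")), fx)
  expect_equal(unname(F2[1, "Hf.v.2"]), 0.5)
  expect_equal(unname(F2[1, "Hr.v.2"]), 0)
  expect_equal(unname(F2[1, "T.v.2"]), 1)
  # clamping pulls out-of-range values to the training bounds
  F3 <- expand_features(matrix(20, 1, 1, dimnames = list(NULL, "v")), fx,
                        clamp = TRUE)
  expect_equal(unname(F3[1, "L.v"]), 1)
  # product features multiply scaled covariates
  env2 <- cbind(a = c(0, 10, 5), b = c(0, 2, 1))
  fxp <- feature_expansion(env2, c("L", "P"))
  Fp <- expand_features(cbind(a = 5, b = 1), fxp)
  expect_equal(unname(Fp[1, "P.a.b"]), 0.25)
  expect_warning(feature_expansion(cbind(a = c(1, 1), b = c(0, 1)), "L"),
                 "constant")
})

test_that("overwhelming regularization zeroes the model", {
  bg <- make_env(100, seed = 2)
  occ <- make_env(20, seed = 3, mean = 0.5)
  fit <- fit_maxent(occ, bg, classes = c("L", "Q"), rm = 1e6,
                    add_samples = FALSE)
  expect_true(all(fit$lambda == 0))
  raw <- predict_raw(fit, bg, weights = fit$bg_weights)
  expect_equal(raw, rep(1 / 100, 100))
})

test_that("fits satisfy the KKT certificate and normalization invariant", {
  for (seed in 1:3) {
    bg <- make_env(150, seed = seed)
    occ <- make_env(25, seed = seed + 10, mean = 0.8)
    fit <- fit_maxent(occ, bg, classes = c("L", "Q", "H"), n_knots = 5,
                      rm = 1, tol = 1e-9)
    expect_true(kkt_check(fit, tol = 1e-4))
    # presences join the training background, which the raw output sums over
    expect_equal(sum(predict_raw(fit, rbind(bg, occ),
                                 weights = fit$bg_weights)), 1)
  }
  # KKT with bias-weighted background too
  bg <- make_env(120, seed = 9)
  occ <- make_env(15, seed = 19, mean = 0.6)
  w <- runif(120, 0.2, 3)
  fitw <- fit_maxent(occ, bg, classes = c("L", "Q"), rm = 1, bg_weights = w,
                     tol = 1e-9)
  expect_true(kkt_check(fitw, tol = 1e-4))
})

test_that("single binary feature obeys the mean-matching KKT bound", {
  env_bg <- matrix(rep(c(0, 1), 50), 100, 1, dimnames = list(NULL, "b"))
  env_occ <- matrix(1, 20, 1, dimnames = list(NULL, "b"))
  fit <- fit_maxent(env_occ, env_bg, classes = "L", rm = 1, tol = 1e-10)
  env_all <- rbind(env_bg, env_occ)
  p_all <- predict_raw(fit, env_all, weights = fit$bg_weights)
  model_mean <- sum(p_all * env_all[, 1])
  expect_lte(abs(model_mean - 1), fit$beta[["L.b"]] + 1e-6)
})

test_that("coordinate descent matches a generic convex-optimizer oracle", {
  bg <- make_env(60, seed = 4)
  occ <- make_env(20, seed = 5, mean = 1)
  fit <- fit_maxent(occ, bg, classes = c("L", "Q"), rm = 1, tol = 1e-12,
                    add_samples = FALSE)
  Fo <- expand_features(occ, fit$fx, clamp = FALSE)
  Fb <- expand_features(bg, fit$fx, clamp = FALSE)
  or <- maxent_oracle(Fo, Fb, fit$beta)
  expect_lt(abs(fit$objective - or$objective), 1e-5)
  expect_lt(max(abs(fit$lambda - or$lambda)), 1e-3)
})

test_that("raw predictions are log-linear and projection is consistent", {
  bg <- make_env(100, seed = 6)
  occ <- make_env(30, seed = 7, mean = 0.7)
  fit <- fit_maxent(occ, bg, classes = "L", rm = 0.5)
  # monotone in an active feature
  j <- names(which(fit$lambda != 0))[1]
  cov <- sub("^L\\.", "", j)
  grid <- matrix(seq(-2, 2, length.out = 50), 50, 2,
                 dimnames = list(NULL, colnames(bg)))
  grid[, setdiff(colnames(bg), cov)] <- 0
  r <- predict_raw(fit, grid)
  expect_true(all(diff(r) > 0) || all(diff(r) < 0))
  # projecting onto the training stack reproduces predict_raw up to renorm
  stack <- list(v1 = grid_raster(matrix(bg[, 1], 10), 0, 0, 1),
                v2 = grid_raster(matrix(bg[, 2], 10), 0, 0, 1))
  pr <- project_model(fit, stack)
  raw <- predict_raw(fit, bg)
  expect_equal(as.vector(pr$values), raw / sum(raw))
  # clamped projection beyond the training max equals the boundary prediction
  hi <- matrix(c(99, 0), 1, 2, dimnames = list(NULL, c("v1", "v2")))
  at_max <- matrix(c(fit$fx$max[["v1"]], 0), 1, 2,
                   dimnames = list(NULL, c("v1", "v2")))
  expect_equal(predict_raw(fit, hi, clamp = TRUE),
               predict_raw(fit, at_max, clamp = TRUE))
})

test_that("saturated hinge features yield a constant shifted projection", {
  env <- matrix(seq(0, 1, length.out = 50), 50, 1, dimnames = list(NULL, "v"))
  fx <- feature_expansion(env, "H", n_knots = 3)
  # uniform shift far beyond the training range saturates every hinge
  shifted <- env + 10
  F <- expand_features(shifted, fx, clamp = TRUE)
  expect_true(all(apply(F, 2, function(x) length(unique(x)) == 1)))
})

test_that("model JSON store round-trips predictions", {
  bg <- make_env(80, seed = 8)
  occ <- make_env(20, seed = 9, mean = 0.5)
  fit <- fit_maxent(occ, bg, classes = c("L", "Q", "H"), n_knots = 4, rm = 1.5)
  p <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(fit, p)
  fit2 <- read_maxent_json(p)
  expect_equal(predict_raw(fit2, bg), predict_raw(fit, bg))
  expect_equal(fit2$rm, fit$rm)
})
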