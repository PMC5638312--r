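#' Feature expansion specification
#'
#' Defines how raw covariates become maxent features. Covariates are min-max
#' scaled to [0,1] using training ranges; classes are L (scaled covariate),
#' Q (its square), P (pairwise products), H (forward and reverse hinges at
#' evenly spaced knots, scaled to [0,1]) and T (step indicators at the same
#' knots).
#'
#' @param env training covariate matrix (points x covariates) supplying the
#'   scaling ranges; columns must be named.
#' @param classes subset of `c("L","Q","P","H","T")`.
#' @param n_knots hinge/threshold knots per covariate per direction.
#' @return object of class `feature_expansion`.
#' @export
feature_expansion <- function(env, classes = c("L", "Q", "H"), n_knots = 50) {
  env <- as.matrix(env)
  if (is.null(colnames(env))) colnames(env) <- paste0("v", seq_len(ncol(env)))
  classes <- match.arg(classes, c("L", "Q", "P", "H", "T"), several.ok = TRUE)
  mn <- apply(env, 2, min); mx <- apply(env, 2, max)
  const <- mx - mn <= 0
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(env)[const], collapse = ", "))
    mn <- mn[!const]; mx <- mx[!const]
  }
  if (!length(mn)) stop("no non-constant covariates")
  structure(list(classes = classes, min = mn, max = mx,
                 knots = seq_len(n_knots) / (n_knots + 1),
                 covariates = names(mn)),
            class = "feature_expansion")
}

#' Expand covariates into the maxent design matrix
#'
#' @param values covariate matrix (points x covariates) containing at least
#'   the expansion's covariates (matched by name).
#' @param fx a [feature_expansion()].
#' @param clamp clamp values outside the training range to [0,1] after
#'   scaling (projection semantics); if `FALSE` scaled values may leave [0,1].
#' @return numeric design matrix; attribute `"class_of"` labels each column
#'   with its feature class.
#' @export
expand_features <- function(values, fx, clamp = TRUE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) && ncol(values) == length(fx$covariates))
    colnames(values) <- fx$covariates
  miss <- setdiff(fx$covariates, colnames(values))
  if (length(miss)) stop("missing covariate layer(s): ", paste(miss, collapse = ", "))
  v <- values[, fx$covariates, drop = FALSE]
  if (any(!is.finite(v))) stop("non-finite covariate values")
  s <- sweep(sweep(v, 2, fx$min), 2, fx$max - fx$min, "/")
  if (clamp) s <- pmin(pmax(s, 0), 1)
  cols <- list(); klass <- character()
  nm <- fx$covariates
  if ("L" %in% fx$classes) {
    cols$L <- s
    colnames(cols$L) <- paste0("L.", nm)
    klass <- c(klass, rep("L", length(nm)))
  }
  if ("Q" %in% fx$classes) {
    cols$Q <- s^2
    colnames(cols$Q) <- paste0("Q.", nm)
    klass <- c(klass, rep("Q", length(nm)))
  }
  if ("P" %in% fx$classes && length(nm) >= 2) {
    pr <- utils::combn(seq_along(nm), 2)
    P <- s[, pr[1, ], drop = FALSE] * s[, pr[2, ], drop = FALSE]
    colnames(P) <- paste0("P.", nm[pr[1, ]], ".", nm[pr[2, ]])
    cols$P <- P
    klass <- c(klass, rep("P", ncol(P)))
  }
  if ("H" %in% fx$classes) {
    H <- lapply(seq_along(nm), function(i) {
      fwd <- vapply(fx$knots, function(t) pmax(0, s[, i] - t) / (1 - t),
                    numeric(nrow(s)))
      rev <- vapply(fx$knots, function(t) pmax(0, t - s[, i]) / t,
                    numeric(nrow(s)))
      m <- cbind(matrix(fwd, nrow(s)), matrix(rev, nrow(s)))
      colnames(m) <- c(paste0("Hf.", nm[i], ".", seq_along(fx$knots)),
                       paste0("Hr.", nm[i], ".", seq_along(fx$knots)))
      m
    })
    cols$H <- do.call(cbind, H)
    klass <- c(klass, rep("H", ncol(cols$H)))
  }
  if ("T" %in% fx$classes) {
    T_ <- lapply(seq_along(nm), function(i) {
      m <- vapply(fx$knots, function(t) as.numeric(s[, i] > t), numeric(nrow(s)))
      m <- matrix(m, nrow(s))
      colnames(m) <- paste0("T.", nm[i], ".", seq_along(fx$knots))
      m
    })
    cols$T <- do.call(cbind, T_)
    klass <- c(klass, rep("T", ncol(cols$T)))
  }
  out <- do.call(cbind, unname(cols))
  attr(out, "class_of") <- klass
  out
}

# published default regularization schedules: beta_class as a function of the
# occurrence sample size m, linearly interpolated and clamped at the ends
beta_schedule <- function(class, m) {
  interp <- function(xs, ys) stats::approx(xs, ys, xout = min(max(m, xs[1]), xs[length(xs)]))$y
  switch(class,
         L = interp(c(0, 10, 30, 100), c(1.0, 1.0, 0.2, 0.05)),
         Q = interp(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
         P = interp(c(0, 10, 17, 30, 100), c(2.6, 1.6, 1.0, 0.5, 0.1)),
         H = 0.5,
         T = interp(c(0, 100), c(2.0, 1.0)),
         stop("unknown feature class ", class))
}

#' Fit an l1-regularized maximum-entropy distribution model
#'
#' Minimizes `-mean_occ(lambda . f) + log sum_bg w_b exp(lambda . f_b) +
#' sum_j beta_j |lambda_j|` by deterministic cyclic coordinate descent
#' (compiled; fixed feature order, exact-objective backtracking, convergence
#' when a full cycle decreases the objective by < `tol`). Per-feature
#' penalties follow the published default schedules:
#' `beta_j = RM * beta_class(m) * s_j / sqrt(m)` with `s_j` the feature
#' standard deviation over the occurrence sample (floored at 0.05 since
#' features live in [0,1]) and m the occurrence count.
#'
#' @param occ_env,bg_env covariate matrices (points x covariates) for
#'   occurrences and background; scaling ranges come from their union.
#' @param classes feature classes, see [feature_expansion()].
#' @param rm regularization multiplier (> 0).
#' @param bg_weights optional positive background weights (e.g. a sampling
#'   bias grid sampled at background cells); normalized internally.
#' @param n_knots hinge/threshold knots.
#' @param tol,max_cycles optimizer controls.
#' @param add_samples include the occurrence points in the fitting background
#'   (the reference implementation's default). This guarantees a finite
#'   optimum even when occurrences are separable from the background in
#'   feature space; with `FALSE`, a separable configuration can push weights
#'   toward infinity and the fit stops at `max_cycles` unconverged.
#' @return object of class `maxent_fit`: `lambda`, `beta`, `fx`, `logZ`,
#'   `grad` (smooth-part gradient at the solution, for the KKT certificate),
#'   `m`, `bg_weights`, `objective`.
#' @export
fit_maxent <- function(occ_env, bg_env, classes = c("L", "Q", "H"), rm = 1,
                       bg_weights = NULL, n_knots = 50, tol = 1e-7,
                       max_cycles = 2000, add_samples = TRUE) {
  occ_env <- as.matrix(occ_env); bg_env <- as.matrix(bg_env)
  m <- nrow(occ_env)
  if (m < 2) stop("need >= 2 occurrences")
  if (nrow(bg_env) < m) stop("background must be at least as large as occurrences")
  if (rm <= 0) stop("RM must be positive")
  fx <- feature_expansion(rbind(occ_env, bg_env), classes, n_knots)
  Fo <- expand_features(occ_env, fx, clamp = FALSE)
  Fb <- expand_features(bg_env, fx, clamp = FALSE)
  fit_maxent_features(Fo, Fb, attr(Fb, "class_of"), fx, rm, bg_weights,
                      tol, max_cycles, add_samples)
}

# core fit on prebuilt design matrices (reused by the tuning grid)
fit_maxent_features <- function(Fo, Fb, class_of, fx, rm, bg_weights = NULL,
                                tol = 1e-7, max_cycles = 2000,
                                add_samples = TRUE) {
  m <- nrow(Fo)
  if (is.null(bg_weights)) bg_weights <- rep(1, nrow(Fb))
  if (any(bg_weights <= 0)) stop("background weights must be positive")
  if (add_samples) {
    # presences join the background with neutral (floor) bias weight
    Fb <- rbind(Fb, Fo)
    bg_weights <- c(bg_weights, rep(min(bg_weights), m))
  }
  w <- bg_weights / sum(bg_weights)
  sj <- pmax(apply(Fo, 2, sd), 0.05)
  beta <- rm * vapply(class_of, beta_schedule, 0, m = m) * sj / sqrt(m)
  res <- maxent_cd(Fb, colMeans(Fo), log(w), beta, tol, max_cycles)
  lambda <- setNames(as.numeric(res$lambda), colnames(Fb))
  structure(list(lambda = lambda, beta = setNames(beta, colnames(Fb)),
                 class_of = class_of, fx = fx, rm = rm, m = m,
                 logZ = res$logZ, grad = setNames(as.numeric(res$grad), colnames(Fb)),
                 objective = res$objective, converged = res$converged,
                 bg_weights = w), class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat("maxent_fit: RM =", x$rm, " classes =", paste(x$fx$classes, collapse = ""),
      " m =", x$m, " nonzero weights =", sum(x$lambda != 0), "/",
      length(x$lambda), "\n")
  invisible(x)
}

#' KKT certificate of a maxent fit
#'
#' At an exact solution, every zero-weight feature satisfies |grad_j| <=
#' beta_j and every active feature satisfies grad_j + beta_j sign(lambda_j)
#' = 0 (within `tol`).
#'
#' @param fit a `maxent_fit`.
#' @param tol slack.
#' @return `TRUE`/`FALSE`; attribute `"worst"` gives the largest violation.
#' @export
kkt_check <- function(fit, tol = 1e-4) {
  g <- fit$grad; b <- fit$beta; l <- fit$lambda
  viol <- ifelse(l == 0, pmax(abs(g) - b, 0), abs(g + b * sign(l)))
  ok <- all(viol <= tol)
  attr(ok, "worst") <- max(viol)
  ok
}

#' Raw (relative occurrence rate) prediction
#'
#' `w * exp(lambda . f) / Z` with the training-background normalizer Z; over
#' the training background (default weights = the stored bias weights) the
#' values sum to exactly 1.
#'
#' @param fit a `maxent_fit`.
#' @param env covariate matrix for the prediction points.
#' @param weights per-point bias weights (default 1; pass the stored
#'   `fit$bg_weights` to reproduce training-background predictions).
#' @param clamp clamp covariates to the training range.
#' @return numeric vector of ROR values.
#' @export
predict_raw <- function(fit, env, weights = NULL, clamp = TRUE) {
  F <- expand_features(env, fit$fx, clamp = clamp)
  if (!identical(colnames(F), names(fit$lambda))) stop("feature mismatch")
  if (is.null(weights)) weights <- rep(1, nrow(F))
  as.vector(weights * exp(F %*% fit$lambda - fit$logZ))
}

#' Project a fitted model onto a covariate raster stack
#'
#' Features are computed with the training scaling; out-of-range cells are
#' clamped to the training [min, max] when `clamp` is set. The output raster
#' holds raw values renormalized to sum 1 over the stack's jointly valid
#' cells.
#'
#' @param fit a `maxent_fit`.
#' @param stack named list of `grid_raster` layers covering all model
#'   covariates.
#' @param clamp clamping flag.
#' @return a `grid_raster` of relative occurrence rates.
#' @export
project_model <- function(fit, stack, clamp = TRUE) {
  miss <- setdiff(fit$fx$covariates, names(stack))
  if (length(miss)) stop("missing covariate layer(s): ", paste(miss, collapse = ", "))
  tmpl <- stack[[1]]
  V <- vapply(stack[fit$fx$covariates], function(r) as.vector(r$values),
              numeric(length(tmpl$values)))
  valid <- which(stats::complete.cases(V))
  env <- matrix(V[valid, ], length(valid), dimnames = list(NULL, fit$fx$covariates))
  raw <- predict_raw(fit, env, clamp = clamp)
  raw <- raw / sum(raw)
  v <- tmpl$values; v[] <- NA_real_; v[valid] <- raw
  grid_raster(v, tmpl$xll, tmpl$yll, tmpl$cellsize)
}

#' Store / load a fitted maxent model as JSON
#' @param fit a `maxent_fit`.
#' @param path file path.
#' @export
write_maxent_json <- function(fit, path) {
  doc <- list(lambda = as.list(fit$lambda), beta = as.list(fit$beta),
              class_of = fit$class_of, rm = fit$rm, m = fit$m,
              logZ = fit$logZ,
              fx = list(classes = fit$fx$classes, min = as.list(fit$fx$min),
                        max = as.list(fit$fx$max), knots = fit$fx$knots,
                        covariates = fit$fx$covariates))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_json
#' @export
read_maxent_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fx <- structure(list(classes = doc$fx$classes,
                       min = unlist(doc$fx$min), max = unlist(doc$fx$max),
                       knots = doc$fx$knots, covariates = doc$fx$covariates),
                  class = "feature_expansion")
  structure(list(lambda = unlist(doc$lambda), beta = unlist(doc$beta),
                 class_of = doc$class_of, fx = fx, rm = doc$rm, m = doc$m,
                 logZ = doc$logZ, grad = NULL, objective = NA_real_,
                 converged = NA, bg_weights = NULL), class = "maxent_fit")
}
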