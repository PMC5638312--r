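#' Block partition of occurrences and background into four spatial bins
#'
#' Occurrences are split at their median latitude (ties resolved by record
#' index), then each half at its own median longitude, giving four bins whose
#' sizes differ by at most one. Background points are assigned by the same
#' boundary lines; a point exactly on a boundary goes to the lower bin.
#'
#' @param occ data.frame with `lon`, `lat` (>= 4 rows).
#' @param bg data.frame with `lon`, `lat`.
#' @return list with integer vectors `occ_fold`, `bg_fold` (values 1-4) and
#'   the boundary lines used.
#' @export
block_partition <- function(occ, bg) {
  occ <- occ_frame(occ)
  n <- nrow(occ)
  if (n < 4) stop("block partition needs >= 4 occurrences")
  ord <- order(occ$lat, seq_len(n))
  nlow <- ceiling(n / 2)
  low <- ord[seq_len(nlow)]; high <- ord[-seq_len(nlow)]
  lat_b <- max(occ$lat[low])
  split_lon <- function(idx) {
    o <- idx[order(occ$lon[idx], idx)]
    nl <- ceiling(length(o) / 2)
    list(w = o[seq_len(nl)], e = o[-seq_len(nl)], lon_b = max(occ$lon[o[seq_len(nl)]]))
  }
  sl <- split_lon(low); sh <- split_lon(high)
  occ_fold <- integer(n)
  occ_fold[sl$w] <- 1L; occ_fold[sl$e] <- 2L
  occ_fold[sh$w] <- 3L; occ_fold[sh$e] <- 4L
  bg_fold <- ifelse(bg$lat <= lat_b,
                    ifelse(bg$lon <= sl$lon_b, 1L, 2L),
                    ifelse(bg$lon <= sh$lon_b, 3L, 4L))
  list(occ_fold = occ_fold, bg_fold = as.integer(bg_fold),
       lat_boundary = lat_b, lon_boundaries = c(low = sl$lon_b, high = sh$lon_b))
}

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a random positive scores above a random negative; ties
#' count one half.
#'
#' @param pos,neg numeric score vectors (both non-empty).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both score sets must be non-empty")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Threshold-dependent omission rates
#'
#' `OR_MTP`: fraction of test scores strictly below the minimum training
#' score (pixels at or above the threshold count as suitable). `OR_10`:
#' fraction strictly below the ceiling(0.1 n)-th smallest training score,
#' i.e. the threshold excluding the lowest-scoring 10% of training presences.
#'
#' @param train_scores,test_scores raw suitability at training and test
#'   presences.
#' @return named numeric `c(OR_MTP, OR_10)`.
#' @export
omission_rates <- function(train_scores, test_scores) {
  if (!length(train_scores) || !length(test_scores)) stop("empty score set")
  mtp <- min(train_scores)
  thr10 <- sort(train_scores)[ceiling(0.1 * length(train_scores))]
  c(OR_MTP = mean(test_scores < mtp), OR_10 = mean(test_scores < thr10))
}

#' Small-sample Akaike criterion
#'
#' AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1); NA when n <= k + 1 (correction
#' undefined).
#'
#' @param k number of (nonzero) parameters.
#' @param n sample size.
#' @param lnL log-likelihood.
#' @return AICc value.
#' @export
aicc_formula <- function(k, n, lnL) {
  if (n > k + 1) 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1) else NA_real_
}

#' Small-sample Akaike criterion for a maxent fit
#'
#' Raw predictions are standardized to sum 1 over the study grid's valid
#' cells; lnL is the summed log standardized ROR at the occurrences; k counts
#' nonzero feature weights; AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1), undefined
#' (NA) when n <= k + 1.
#'
#' @param fit a `maxent_fit`.
#' @param occ_env covariates at the n occurrence points.
#' @param grid_env covariates at all valid study-grid cells.
#' @return list with `k`, `lnL`, `AICc`.
#' @export
aicc <- function(fit, occ_env, grid_env) {
  n <- nrow(as.matrix(occ_env))
  k <- sum(fit$lambda != 0)
  raw_grid <- predict_raw(fit, grid_env)
  raw_occ <- predict_raw(fit, occ_env)
  lnL <- sum(log(raw_occ / sum(raw_grid)))
  list(k = k, lnL = lnL, AICc = aicc_formula(k, n, lnL))
}

#' Tune feature classes and regularization by block cross-validation
#'
#' For every (feature-class set, regularization multiplier) pair: a full-data
#' fit supplies k and AICc (standardized over the study grid), and 4-fold
#' block cross-validation supplies fold-averaged AUC_TEST, AUC_DIFF =
#' AUC_TRAIN - AUC_TEST, OR_MTP and OR_10. Delta AICc is taken against the
#' table minimum and the selected model is the Delta AICc = 0 record (ties:
#' smaller k, then smaller RM).
#'
#' @param occ data.frame of occurrences (`lon`, `lat`).
#' @param stack named list of covariate `grid_raster` layers.
#' @param n_bg number of background cells sampled (without replacement when
#'   possible) from the valid cells.
#' @param fc_set character vector of feature-class combinations, e.g.
#'   `c("L","LQ","H","LQH","LQHP","LQHPT")`.
#' @param rm_grid numeric vector of regularization multipliers.
#' @param bias optional `grid_raster` of sampling-bias weights for the
#'   background.
#' @param n_knots hinge/threshold knots.
#' @param seed RNG seed for the background sample.
#' @param tol,max_cycles optimizer controls.
#' @return list: `table` (one row per FC x RM with the evaluation metrics and
#'   `dAICc`), `best` (refitted `maxent_fit` at the selected settings),
#'   `selected` (row index), `folds`, `bg_cells`.
#' @export
tune_enm <- function(occ, stack, n_bg = 10000,
                     fc_set = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
                     rm_grid = seq(1, 5, by = 0.5), bias = NULL,
                     n_knots = 50, seed = NULL, tol = 1e-7, max_cycles = 2000) {
  occ <- occ_frame(occ)
  tmpl <- stack[[1]]
  V <- vapply(stack, function(r) as.vector(r$values), numeric(length(tmpl$values)))
  colnames(V) <- names(stack)
  valid <- which(stats::complete.cases(V))
  # occurrences -> containing cells
  rc <- cell_of(tmpl, occ$lon, occ$lat)
  cells <- (rc[, "col"] - 1L) * nrow(tmpl$values) + rc[, "row"]
  ok <- !is.na(cells) & cells %in% valid
  if (any(!ok)) warning(sum(!ok), " occurrence(s) off the valid grid dropped")
  occ <- occ[ok, , drop = FALSE]; cells <- cells[ok]
  occ_env <- V[cells, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  bg_cells <- if (length(valid) > n_bg) sort(sample(valid, n_bg)) else valid
  bg_env <- V[bg_cells, , drop = FALSE]
  cc <- cell_centers(tmpl)
  bg_xy <- data.frame(lon = cc$lon_mat[bg_cells], lat = cc$lat_mat[bg_cells])
  bw <- if (!is.null(bias)) as.vector(bias$values)[bg_cells] else NULL
  folds <- block_partition(occ, bg_xy)

  fx <- feature_expansion(rbind(occ_env, bg_env), c("L", "Q", "P", "H", "T"),
                          n_knots)
  Fo <- expand_features(occ_env, fx, clamp = FALSE)
  Fb <- expand_features(bg_env, fx, clamp = FALSE)
  Fg <- expand_features(V[valid, , drop = FALSE], fx, clamp = FALSE)
  class_of <- attr(Fb, "class_of")

  sub_fx <- function(fc) {
    cls <- strsplit(fc, "")[[1]]
    keep <- class_of %in% cls
    fx2 <- fx; fx2$classes <- cls
    list(keep = keep, fx = fx2)
  }
  grid <- expand.grid(fc = fc_set, rm = rm_grid, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fc <- grid$fc[g]; rm <- grid$rm[g]
    sb <- sub_fx(fc)
    rec <- data.frame(fc = fc, rm = rm, AUC_TEST = NA_real_, AUC_DIFF = NA_real_,
                      OR_MTP = NA_real_, OR_10 = NA_real_, k = NA_integer_,
                      lnL = NA_real_, AICc = NA_real_, stringsAsFactors = FALSE)
    res <- tryCatch({
      full <- fit_maxent_features(Fo[, sb$keep, drop = FALSE],
                                  Fb[, sb$keep, drop = FALSE],
                                  class_of[sb$keep], sb$fx, rm, bw,
                                  tol, max_cycles)
      raw_grid <- exp(Fg[, sb$keep, drop = FALSE] %*% full$lambda)
      raw_occ_full <- exp(Fo[, sb$keep, drop = FALSE] %*% full$lambda)
      lnL <- sum(log(raw_occ_full / sum(raw_grid)))
      k <- sum(full$lambda != 0)
      aic <- aicc_formula(k, nrow(Fo), lnL)
      auc_te <- auc_tr <- or1 <- or2 <- numeric(4)
      for (f in 1:4) {
        tr_o <- folds$occ_fold != f; te_o <- !tr_o
        tr_b <- folds$bg_fold != f; te_b <- !tr_b
        fit <- fit_maxent_features(Fo[tr_o, sb$keep, drop = FALSE],
                                   Fb[tr_b, sb$keep, drop = FALSE],
                                   class_of[sb$keep], sb$fx, rm,
                                   if (!is.null(bw)) bw[tr_b], tol, max_cycles)
        s_occ_tr <- as.vector(exp(Fo[tr_o, sb$keep, drop = FALSE] %*% fit$lambda))
        s_occ_te <- as.vector(exp(Fo[te_o, sb$keep, drop = FALSE] %*% fit$lambda))
        s_bg_tr <- as.vector(exp(Fb[tr_b, sb$keep, drop = FALSE] %*% fit$lambda))
        s_bg_te <- as.vector(exp(Fb[te_b, sb$keep, drop = FALSE] %*% fit$lambda))
        auc_tr[f] <- auc_rank(s_occ_tr, s_bg_tr)
        auc_te[f] <- auc_rank(s_occ_te, if (length(s_bg_te)) s_bg_te else s_bg_tr)
        or <- omission_rates(s_occ_tr, s_occ_te)
        or1[f] <- or["OR_MTP"]; or2[f] <- or["OR_10"]
      }
      rec$AUC_TEST <- mean(auc_te); rec$AUC_DIFF <- mean(auc_tr - auc_te)
      rec$OR_MTP <- mean(or1); rec$OR_10 <- mean(or2)
      rec$k <- k; rec$lnL <- lnL; rec$AICc <- aic
      rec
    }, error = function(e) {
      warning("fit failed for FC=", fc, " RM=", rm, ": ", conditionMessage(e))
      rec
    })
    rows[[g]] <- res
  }
  tab <- do.call(rbind, rows)
  tab$dAICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  cand <- which(!is.na(tab$dAICc) & tab$dAICc == 0)
  cand <- cand[order(tab$k[cand], tab$rm[cand])]
  sel <- cand[1]
  sb <- sub_fx(tab$fc[sel])
  best <- fit_maxent_features(Fo[, sb$keep, drop = FALSE],
                              Fb[, sb$keep, drop = FALSE],
                              class_of[sb$keep], sb$fx, tab$rm[sel], bw,
                              tol, max_cycles)
  list(table = tab, best = best, selected = sel, folds = folds,
       bg_cells = bg_cells)
}

#' Schoener's D niche overlap between two suitability rasters
#'
#' Each raster is normalized to sum 1 over the jointly valid cells, then
#' D = 1 - 0.5 * sum |p1 - p2|: 1 for identical surfaces, 0 for disjoint
#' support. Symmetric, and invariant to positive rescaling of either raster.
#'
#' @param r1,r2 `grid_raster` objects on the same grid.
#' @return D in [0, 1].
#' @export
schoener_d <- function(r1, r2) {
  if (!same_grid(r1, r2)) stop("rasters on different grids")
  v1 <- as.vector(r1$values); v2 <- as.vector(r2$values)
  joint <- !is.na(v1) & !is.na(v2)
  if (!any(joint)) stop("no jointly valid cells")
  s1 <- sum(v1[joint]); s2 <- sum(v2[joint])
  if (s1 <= 0 || s2 <= 0) stop("all-zero raster over joint cells")
  1 - 0.5 * sum(abs(v1[joint] / s1 - v2[joint] / s2))
}

#' Pairwise Schoener's D matrix
#' @param rasters named list of `grid_raster` objects on one grid.
#' @return symmetric matrix with unit diagonal.
#' @export
schoener_d_matrix <- function(rasters) {
  n <- length(rasters)
  D <- matrix(1, n, n, dimnames = list(names(rasters), names(rasters)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- schoener_d(rasters[[i]], rasters[[j]])
  D
}
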