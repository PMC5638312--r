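#' Specification for simulated multigroup genotypes
#'
#' Balding-Nichols island model: ancestral allele frequencies are Dirichlet
#' draws; each group's frequencies are Dirichlet(p_anc * (1-F)/F) so the
#' expected Wright F_ST among groups equals `F` (the closed-form recovery
#' target used by the estimator tests). Diploid genotypes are drawn iid
#' within groups, then missing calls are masked at the stated rate and
#' group-private alleles injected at the stated rate.
#'
#' @param group_sizes named or unnamed integer vector of accessions per group.
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus in the ancestral pool.
#' @param dirichlet_conc concentration of the ancestral Dirichlet.
#' @param F differentiation parameter in (0, 1), exclusive.
#' @param missing_rate fraction of calls masked as missing.
#' @param private_rate per (group, locus) probability of injecting one copy
#'   of a group-unique allele.
#' @param seed RNG seed.
#' @return object of class `genotype_sim_spec`.
#' @export
genotype_sim_spec <- function(group_sizes = c(60, 60, 60), n_loci = 19,
                              n_alleles = 8, dirichlet_conc = 1, F = 0.15,
                              missing_rate = 0, private_rate = 0, seed = 1) {
  if (F <= 0 || F >= 1) stop("F must be strictly inside (0, 1)")
  if (missing_rate < 0 || missing_rate > 1 || private_rate < 0 || private_rate > 1)
    stop("rates must be in [0, 1]")
  if (any(group_sizes < 1)) stop("group sizes must be >= 1")
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("G", seq_along(group_sizes))
  structure(list(group_sizes = group_sizes, n_loci = n_loci,
                 n_alleles = n_alleles, dirichlet_conc = dirichlet_conc,
                 F = F, missing_rate = missing_rate,
                 private_rate = private_rate, seed = seed),
            class = "genotype_sim_spec")
}

rdirichlet1 <- function(shape) {
  g <- rgamma(length(shape), shape)
  g / sum(g)
}

#' Simulate multigroup diploid genotypes (Balding-Nichols)
#'
#' @param spec a [genotype_sim_spec()].
#' @return list with `gt` (a [genotype_table()]) and `truth` (ancestral and
#'   per-group allele frequencies, F, injected private alleles).
#' @export
simulate_genotypes <- function(spec) {
  set.seed(spec$seed)
  G <- length(spec$group_sizes); N <- sum(spec$group_sizes)
  grp <- rep(names(spec$group_sizes), spec$group_sizes)
  a1 <- a2 <- matrix(NA_integer_, N, spec$n_loci)
  p_anc <- vector("list", spec$n_loci)
  p_grp <- vector("list", spec$n_loci)
  injected <- list()
  for (l in seq_len(spec$n_loci)) {
    p_anc[[l]] <- rdirichlet1(rep(spec$dirichlet_conc, spec$n_alleles))
    pg <- matrix(NA_real_, G, spec$n_alleles)
    for (g in seq_len(G)) {
      pg[g, ] <- rdirichlet1(p_anc[[l]] * (1 - spec$F) / spec$F)
      idx <- which(grp == names(spec$group_sizes)[g])
      a1[idx, l] <- sample.int(spec$n_alleles, length(idx), TRUE, pg[g, ])
      a2[idx, l] <- sample.int(spec$n_alleles, length(idx), TRUE, pg[g, ])
    }
    p_grp[[l]] <- pg
    if (spec$private_rate > 0) {
      for (g in seq_len(G)) {
        if (runif(1) < spec$private_rate) {
          idx <- which(grp == names(spec$group_sizes)[g])
          i <- idx[sample.int(length(idx), 1)]
          code <- spec$n_alleles + g           # allele unique to group g
          if (runif(1) < 0.5) a1[i, l] <- code else a2[i, l] <- code
          injected[[length(injected) + 1]] <-
            data.frame(group = names(spec$group_sizes)[g], locus = l, allele = code)
        }
      }
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(runif(N * spec$n_loci) < spec$missing_rate, N)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  gt <- genotype_table(a1, a2, id = sprintf("acc%03d", seq_len(N)), group = grp,
                       loci = sprintf("SSR%02d", seq_len(spec$n_loci)))
  list(gt = gt,
       truth = list(p_anc = p_anc, p_group = p_grp, F = spec$F,
                    injected = if (length(injected)) do.call(rbind, injected)))
}

#' Specification for a simulated environmental landscape
#'
#' Covariates are Gaussian-smoothed white noise (spatially autocorrelated at
#' the stated kernel length, standardized to mean 0 / sd 1); the true
#' suitability is the log-linear surface exp(coefs . covariates) normalized
#' to sum 1 over the grid.
#'
#' @param n_row,n_col grid dimensions.
#' @param n_cov number of covariate layers.
#' @param autocorr_cells Gaussian smoothing kernel s.d. in cells.
#' @param coefs true log-linear coefficients (length `n_cov`).
#' @param n_occ occurrence count for [sample_occurrences()] users.
#' @param xll,yll,cellsize grid geometry (decimal degrees).
#' @param seed RNG seed.
#' @return object of class `landscape_sim_spec`.
#' @export
landscape_sim_spec <- function(n_row = 60, n_col = 60, n_cov = 4,
                               autocorr_cells = 5,
                               coefs = c(1.5, -1, 0.5, 0)[seq_len(n_cov)],
                               n_occ = 300, xll = 20, yll = 25,
                               cellsize = 0.25, seed = 1) {
  if (length(coefs) != n_cov) stop("coefs length must equal n_cov")
  if (n_row < 2 || n_col < 2) stop("grid must be at least 2 x 2")
  structure(list(n_row = n_row, n_col = n_col, n_cov = n_cov,
                 autocorr_cells = autocorr_cells, coefs = coefs,
                 n_occ = n_occ, xll = xll, yll = yll, cellsize = cellsize,
                 seed = seed),
            class = "landscape_sim_spec")
}

# separable Gaussian smoothing with edge renormalization
smooth_gauss <- function(M, sigma) {
  if (sigma <= 0) return(M)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k * (d <= 3 * sigma)
  }
  Ar <- band(nrow(M)); Ac <- band(ncol(M))
  (Ar %*% M %*% Ac) / (Ar %*% matrix(1, nrow(M), ncol(M)) %*% Ac)
}

#' Simulate an autocorrelated covariate stack and its true suitability
#'
#' @param spec a [landscape_sim_spec()].
#' @return list with `stack` (named list of covariate `grid_raster`s) and
#'   `suitability` (`grid_raster` summing to 1).
#' @export
simulate_landscape <- function(spec) {
  set.seed(spec$seed)
  stack <- list()
  lin <- matrix(0, spec$n_row, spec$n_col)
  for (k in seq_len(spec$n_cov)) {
    M <- smooth_gauss(matrix(rnorm(spec$n_row * spec$n_col), spec$n_row),
                      spec$autocorr_cells)
    M <- (M - mean(M)) / sd(M)
    stack[[paste0("cov", k)]] <- grid_raster(M, spec$xll, spec$yll, spec$cellsize)
    lin <- lin + spec$coefs[k] * M
  }
  suit <- exp(lin)
  suit <- suit / sum(suit)
  list(stack = stack,
       suitability = grid_raster(suit, spec$xll, spec$yll, spec$cellsize))
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability times the
#' optional bias raster (multiplicative, matching the bias-grid weighting
#' used in model fitting); each point lands uniformly inside its cell.
#'
#' @param suitability a `grid_raster` with non-negative values.
#' @param n number of points (> 0).
#' @param bias optional `grid_raster` of relative sampling effort.
#' @param seed RNG seed.
#' @return data.frame with `id`, `lon`, `lat`.
#' @export
sample_occurrences <- function(suitability, n, bias = NULL, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  w <- as.vector(suitability$values)
  if (!is.null(bias)) {
    if (!same_grid(suitability, bias)) stop("bias on a different grid")
    w <- w * as.vector(bias$values)
  }
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("suitability must have positive mass")
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  nr <- nrow(suitability$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cs <- suitability$cellsize
  data.frame(id = seq_len(n),
             lon = suitability$xll + (col - 1L + runif(n)) * cs,
             lat = suitability$yll + (nr - row + runif(n)) * cs)
}

#' Affine per-layer shift of a covariate stack (paleo-climate stand-in)
#'
#' @param stack named list of `grid_raster` layers.
#' @param offsets per-layer additive offsets (length = layers).
#' @param scales per-layer multiplicative factors.
#' @return a stack with the same grids and transformed values.
#' @export
shift_climate <- function(stack, offsets, scales = rep(1, length(stack))) {
  if (length(offsets) != length(stack) || length(scales) != length(stack))
    stop("offsets/scales length must equal the number of layers")
  out <- stack
  for (k in seq_along(stack))
    out[[k]]$values <- stack[[k]]$values * scales[k] + offsets[k]
  out
}

#' Write simulator outputs as plain-text fixtures
#'
#' Produces the genotype CSV, occurrence CSV and ASCII-grid rasters the rest
#' of the pipeline consumes.
#'
#' @param dir output directory (created if absent).
#' @param gt optional [genotype_table()].
#' @param occ optional occurrence data.frame.
#' @param stack optional named raster stack.
#' @return invisible vector of written paths.
#' @export
write_sim_fixtures <- function(dir, gt = NULL, occ = NULL, stack = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(gt)) {
    p <- file.path(dir, "genotypes.csv"); write_genotype_table(gt, p)
    paths <- c(paths, p)
  }
  if (!is.null(occ)) {
    p <- file.path(dir, "occurrences.csv")
    write.table(occ, p, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(stack)) for (nm in names(stack)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
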