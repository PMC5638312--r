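#' Bayesian admixture clustering (Gibbs sampler)
#'
#' STRUCTURE-style admixture model with independent allele frequencies: each
#' allele copy has a latent cluster of origin z; cluster allele frequencies P
#' get a symmetric Dirichlet(lambda) prior; individual membership vectors Q get
#' a Dirichlet(alpha) prior; a single alpha shared by all clusters is updated
#' by random-walk Metropolis on log(alpha) with a uniform prior on (0, 10].
#' All conditionals are conjugate, so the sampler alternates Gibbs updates of
#' Z | (P,Q), P | Z and Q | Z. The estimated log probability of the data uses
#' the harmonic-style correction lnPD = mean(lnL) - var(lnL)/2 over post-burnin
#' sweeps.
#'
#' @param gt a [genotype_table()].
#' @param K number of clusters (>= 1, <= number of accessions).
#' @param burnin,sweeps burn-in and retained MCMC sweeps.
#' @param lambda Dirichlet concentration for allele frequencies (> 0).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param alpha_sd Metropolis step s.d. on log(alpha).
#' @return object of class `admixture_run`: `Q` (posterior-mean memberships,
#'   rows sum to 1), `P` (posterior-mean frequencies per cluster x locus),
#'   `alpha` (posterior mean), `lnPD`, `lnL_trace`, and the call settings.
#' @export
fit_admixture <- function(gt, K, burnin = 200, sweeps = 500, lambda = 1,
                          seed = NULL, alpha_sd = 0.05) {
  N <- length(gt$id); L <- length(gt$loci)
  if (K < 1 || K > N) stop("K must be in 1..", N)
  if (sweeps < 1) stop("sweeps must be >= 1")
  if (lambda <= 0) stop("lambda must be positive")
  if (!is.null(seed)) set.seed(seed)
  labs <- locus_allele_labels(gt)
  I1 <- vapply(seq_len(L), function(l) match(gt$a1[, l], labs[[l]]), integer(N))
  I2 <- vapply(seq_len(L), function(l) match(gt$a2[, l], labs[[l]]), integer(N))
  I1 <- matrix(I1, N); I2 <- matrix(I2, N)

  rdirichlet_rows <- function(shape) {            # rows of independent Dirichlets
    g <- matrix(rgamma(length(shape), as.vector(shape)), nrow(shape))
    g / pmax(rowSums(g), .Machine$double.xmin)
  }
  sample_rows <- function(W) {                    # categorical row-wise
    tot <- rowSums(W)
    u <- runif(nrow(W)) * tot
    z <- integer(nrow(W)); acc <- numeric(nrow(W))
    pick <- rep(TRUE, nrow(W))
    for (k in seq_len(ncol(W))) {
      acc <- acc + W[, k]
      sel <- pick & (u <= acc)
      z[sel] <- k
      pick <- pick & !sel
    }
    z[pick] <- ncol(W)                            # numeric slack
    z
  }

  P <- lapply(seq_len(L), function(l)
    rdirichlet_rows(matrix(lambda, K, length(labs[[l]]))))
  Q <- matrix(1 / K, N, K)
  alpha <- 1
  Z1 <- I1; Z2 <- I2                              # placeholders; overwritten below
  Qsum <- matrix(0, N, K)
  Psum <- lapply(seq_len(L), function(l) matrix(0, K, length(labs[[l]])))
  alpha_sum <- 0
  lnL_trace <- numeric(sweeps)
  ldirich <- function(a, q) {                     # log Dirichlet(alpha,...,alpha) density sum
    N * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * sum(log(q))
  }

  for (s in seq_len(burnin + sweeps)) {
    lnL <- 0
    for (l in seq_len(L)) {
      typed <- which(!is.na(I1[, l]))
      if (!length(typed)) next
      for (copy in 1:2) {
        a <- (if (copy == 1) I1 else I2)[typed, l]
        W <- Q[typed, , drop = FALSE] * t(P[[l]][, a, drop = FALSE])
        lnL <- lnL + sum(log(pmax(rowSums(W), .Machine$double.xmin)))
        z <- sample_rows(W)
        if (copy == 1) Z1[typed, l] <- z else Z2[typed, l] <- z
      }
      # P | Z: Dirichlet(lambda + copy counts per cluster x allele)
      aall <- c(I1[typed, l], I2[typed, l])
      zall <- c(Z1[typed, l], Z2[typed, l])
      cnt <- matrix(0, K, length(labs[[l]]))
      tab <- table(factor(zall, 1:K), factor(aall, seq_along(labs[[l]])))
      cnt[] <- as.numeric(tab)
      P[[l]] <- rdirichlet_rows(lambda + cnt)
    }
    if (K > 1) {
      nik <- matrix(0, N, K)
      for (k in seq_len(K))
        nik[, k] <- rowSums(Z1 == k, na.rm = TRUE) + rowSums(Z2 == k, na.rm = TRUE)
      Q <- rdirichlet_rows(alpha + nik)
      Q <- pmax(Q, 1e-300); Q <- Q / rowSums(Q)
      prop <- alpha * exp(rnorm(1, 0, alpha_sd))
      if (prop <= 10) {                           # uniform prior on (0, 10]
        lacc <- ldirich(prop, Q) - ldirich(alpha, Q) + log(prop) - log(alpha)
        if (log(runif(1)) < lacc) alpha <- prop
      }
    }
    if (s > burnin) {
      t <- s - burnin
      lnL_trace[t] <- lnL
      Qsum <- Qsum + Q
      for (l in seq_len(L)) Psum[[l]] <- Psum[[l]] + P[[l]]
      alpha_sum <- alpha_sum + alpha
    }
  }
  lnPD <- mean(lnL_trace) - var(lnL_trace) / 2
  if (sweeps == 1) lnPD <- lnL_trace
  Qbar <- Qsum / sweeps
  Qbar <- Qbar / rowSums(Qbar)
  rownames(Qbar) <- gt$id
  structure(list(K = K, Q = Qbar,
                 P = lapply(seq_len(L), function(l) {
                   m <- Psum[[l]] / sweeps
                   dimnames(m) <- list(NULL, as.character(labs[[l]])); m
                 }),
                 alpha = alpha_sum / sweeps, lnPD = lnPD,
                 lnL_trace = lnL_trace, seed = seed,
                 burnin = burnin, sweeps = sweeps, lambda = lambda),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("admixture_run: K =", x$K, " lnPD =", format(x$lnPD, digits = 6),
      " alpha =", format(x$alpha, digits = 3), "\n")
  invisible(x)
}

#' Modal cluster assignment from a Q matrix
#' @param run an `admixture_run` (or a Q matrix).
#' @return integer vector of per-accession modal clusters.
#' @export
modal_assignment <- function(run) {
  Q <- if (inherits(run, "admixture_run")) run$Q else run
  apply(Q, 1, which.max)
}

#' Evanno delta-K scan
#'
#' From replicate lnPD values per K: mean L(K) and sd(K); first and second
#' differences L'(K) = L(K) - L(K-1), L''(K) = L(K+1) - 2 L(K) + L(K-1); and
#' delta-K = |L''(K)| / sd(K), defined for interior K with sd > 0. A distinct
#' delta-K peak marks the supported number of clusters.
#'
#' @param runs named list: names are K values (>= 3 consecutive), elements are
#'   numeric vectors of replicate lnPD (>= 2 each).
#' @return data.frame with columns `K`, `mean_lnPD`, `sd_lnPD`, `Lp`, `Lpp`,
#'   `deltaK`.
#' @export
evanno <- function(runs) {
  Ks <- sort(as.integer(names(runs)))
  if (length(Ks) < 3 || any(diff(Ks) != 1L))
    stop("evanno needs >= 3 consecutive K values")
  if (any(vapply(runs, length, 0L) < 2))
    stop("evanno needs >= 2 replicates per K")
  m <- vapply(as.character(Ks), function(k) mean(runs[[k]]), 0)
  s <- vapply(as.character(Ks), function(k) sd(runs[[k]]), 0)
  n <- length(Ks)
  Lp <- c(NA, diff(m))
  Lpp <- c(NA, m[-(1:2)] - 2 * m[2:(n - 1)] + m[1:(n - 2)], NA)
  dK <- ifelse(!is.na(Lpp) & s > 0, abs(Lpp) / s, NA_real_)
  data.frame(K = Ks, mean_lnPD = m, sd_lnPD = s, Lp = Lp, Lpp = Lpp,
             deltaK = dK, row.names = NULL)
}

#' Run replicate admixture fits over a range of K
#'
#' @param gt a [genotype_table()].
#' @param K_range integer vector of consecutive K values.
#' @param reps replicate runs per K.
#' @param seed base seed; run r at K gets seed `seed + 1000*K + r`.
#' @param ... passed to [fit_admixture()] (burnin, sweeps, ...).
#' @return list with `lnPD` (list K -> replicate values), `evanno` table and
#'   `best_runs` (highest-lnPD run per K).
#' @export
admixture_scan <- function(gt, K_range = 2:6, reps = 5, seed = 1, ...) {
  lnPD <- setNames(vector("list", length(K_range)), K_range)
  best <- setNames(vector("list", length(K_range)), K_range)
  for (K in K_range) {
    vals <- numeric(reps)
    for (r in seq_len(reps)) {
      run <- fit_admixture(gt, K, seed = seed + 1000L * K + r, ...)
      vals[r] <- run$lnPD
      if (r == 1 || run$lnPD > max(vals[seq_len(r - 1)])) best[[as.character(K)]] <- run
    }
    lnPD[[as.character(K)]] <- vals
  }
  list(lnPD = lnPD, evanno = evanno(lnPD), best_runs = best)
}

#' Align cluster labels of replicate Q matrices (reporting only)
#'
#' Greedy column matching to the first run: each column of a later Q is
#' matched to the unclaimed reference column with the highest dot product.
#'
#' @param qlist list of Q matrices with identical dimensions.
#' @return list of Q matrices with permuted columns.
#' @export
align_q <- function(qlist) {
  ref <- qlist[[1]]
  lapply(qlist, function(Q) {
    K <- ncol(Q)
    sim <- crossprod(ref, Q)                     # ref-cluster x this-cluster
    perm <- integer(K); taken <- rep(FALSE, K)
    for (k in order(-apply(sim, 2, max))) {
      j <- order(-sim[, k])
      j <- j[!taken[j]][1]
      perm[j] <- k; taken[j] <- TRUE
    }
    Q[, perm, drop = FALSE]
  })
}

#' Write a Q matrix as TSV
#' @param run an `admixture_run`.
#' @param path output path.
#' @export
write_q_matrix <- function(run, path) {
  df <- data.frame(id = rownames(run$Q), round(run$Q, 5), check.names = FALSE)
  names(df)[-1] <- paste0("Q", seq_len(run$K))
  write_tsv_table(df, path)
}
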