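# shared fixtures and independent oracles (kept deliberately naive)

# tiny genotype table from explicit allele pairs:
# calls[[accession]][[locus]] = c(a, b) or NA
toy_gt <- function(calls, group = NULL, id = NULL, lon = NULL, lat = NULL) {
  n <- length(calls); L <- length(calls[[1]])
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (l in seq_len(L)) {
    cl <- calls[[i]][[l]]
    if (!is.null(cl) && !anyNA(cl)) { a1[i, l] <- cl[1]; a2[i, l] <- cl[2] }
  }
  genotype_table(a1, a2,
                 id = if (is.null(id)) paste0("i", seq_len(n)) else id,
                 group = if (is.null(group)) rep("A", n) else group,
                 loci = paste0("L", seq_len(L)), lon = lon, lat = lat)
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# best label-permutation accuracy of a clustering against truth
perm_accuracy <- function(assign, truth) {
  K <- max(truth)
  max(vapply(all_perms(seq_len(K)), function(p) mean(p[truth] == assign), 0))
}

# exhaustive rarefaction oracle: expected allele count in all C(N, g) subsets
enum_ar <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(s) length(unique(copies[s]))))
}

# exhaustive private-richness oracle over all subsample pairs of two groups
enum_par <- function(counts_focal, counts_other, g) {
  cf <- rep(seq_along(counts_focal), counts_focal)
  co <- rep(seq_along(counts_other), counts_other)
  sf <- utils::combn(length(cf), g); so <- utils::combn(length(co), g)
  tot <- 0
  for (i in seq_len(ncol(sf))) for (j in seq_len(ncol(so)))
    tot <- tot + length(setdiff(unique(cf[sf[, i]]), unique(co[so[, j]])))
  tot / (ncol(sf) * ncol(so))
}

# independent brute-force distance AMOVA for the gene-copy convention
brute_amova <- function(gt) {
  hap <- rbind(gt$a1, gt$a2)
  grp <- c(gt$group, gt$group)
  N <- nrow(hap)
  d2 <- function(u, v) {
    both <- !is.na(hap[u, ]) & !is.na(hap[v, ])
    sum(hap[u, both] != hap[v, both])
  }
  SSt <- 0
  for (u in seq_len(N - 1)) for (v in (u + 1):N) SSt <- SSt + d2(u, v)
  SSt <- SSt / N
  SSw <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g); s <- 0
    if (length(idx) > 1)
      for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx))
        s <- s + d2(idx[a], idx[b])
    SSw <- SSw + s / length(idx)
  }
  G <- length(unique(grp))
  MSa <- (SSt - SSw) / (G - 1); MSw <- SSw / (N - G)
  ng <- as.vector(table(grp))
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  s2a <- (MSa - MSw) / n0; s2w <- MSw
  list(SSa = SSt - SSw, SSw = SSw, s2a = s2a, s2w = s2w,
       fst = s2a / (s2a + s2w))
}

# split-sign convex-optimizer oracle for the maxent objective
maxent_oracle <- function(Fo, Fb, beta, w = NULL) {
  if (is.null(w)) w <- rep(1 / nrow(Fb), nrow(Fb))
  mu <- colMeans(Fo); p <- ncol(Fb)
  obj <- function(th) {
    lam <- th[1:p] - th[(p + 1):(2 * p)]
    -sum(mu * lam) + log(sum(w * exp(Fb %*% lam))) +
      sum(beta * (th[1:p] + th[(p + 1):(2 * p)]))
  }
  o <- stats::optim(rep(0, 2 * p), obj, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 5000, factr = 10))
  list(lambda = o$par[1:p] - o$par[(p + 1):(2 * p)], objective = o$value)
}

# environment matrices for a landscape + occurrences (test-side plumbing)
land_env <- function(land, occ = NULL) {
  V <- vapply(land$stack, function(r) as.vector(r$values),
              numeric(length(land$stack[[1]]$values)))
  colnames(V) <- names(land$stack)
  out <- list(grid = V)
  if (!is.null(occ)) {
    tmpl <- land$stack[[1]]
    rc <- cell_of(tmpl, occ$lon, occ$lat)
    cells <- (rc[, "col"] - 1L) * nrow(tmpl$values) + rc[, "row"]
    out$occ <- V[cells, , drop = FALSE]
  }
  out
}
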