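#' Between-group differentiation from gene-diversity components
#'
#' G_GT = (H_T - H_G) / H_T: the share of total gene diversity attributable to
#' differences between groups. 0 when groups have identical frequencies, 1 when
#' groups are fixed for different alleles.
#'
#' @param ht total gene diversity H_T.
#' @param hg mean within-group gene diversity H_G.
#' @return numeric vector; NA where H_T = 0.
#' @export
gst_from_components <- function(ht, hg) ifelse(ht > 0, (ht - hg) / ht, NA_real_)

#' Percentage of molecular variance within and among groups
#' @param sigma_among,sigma_within AMOVA variance components.
#' @return named numeric `c(among, within)` summing to 100.
#' @export
amova_percentages <- function(sigma_among, sigma_within) {
  tot <- sigma_among + sigma_within
  c(among = 100 * sigma_among / tot, within = 100 * sigma_within / tot)
}

#' Nei's decomposition of gene diversity
#'
#' Per locus: group allele frequencies x_ga, unweighted mean frequencies
#' x_bar_a, total diversity H_T = 1 - sum x_bar_a^2, mean within-group
#' diversity H_G, D_GT = H_T - H_G and G_GT = D_GT / H_T (equal group weights,
#' Nei-1973 convention). Loci untyped in any group are dropped with a warning.
#'
#' @param ac an `allele_counts` object with >= 2 groups.
#' @return data.frame with columns `locus`, `HT`, `HG`, `DGT`, `GGT`,
#'   `within` (= 1 - GGT) plus an unweighted `Mean` row.
#' @export
nei_decomposition <- function(ac) {
  if (length(ac$groups) < 2) stop("nei_decomposition needs >= 2 groups")
  keep <- colSums(ac$n_typed == 0L) == 0L
  if (any(!keep))
    warning("dropping loci untyped in some group: ",
            paste(ac$loci[!keep], collapse = ", "))
  loci <- ac$loci[keep]
  HT <- HG <- numeric(length(loci))
  for (k in seq_along(loci)) {
    m <- ac$counts[[loci[k]]]
    x <- m / rowSums(m)
    HT[k] <- gene_diversity(colMeans(x))
    HG[k] <- mean(apply(x, 1, gene_diversity))
  }
  DGT <- HT - HG
  GGT <- gst_from_components(HT, HG)
  out <- data.frame(locus = loci, HT = HT, HG = HG, DGT = DGT, GGT = GGT,
                    within = 1 - GGT, stringsAsFactors = FALSE)
  rbind(out, data.frame(locus = "Mean", HT = mean(HT), HG = mean(HG),
                        DGT = mean(DGT), GGT = mean(GGT, na.rm = TRUE),
                        within = mean(1 - GGT, na.rm = TRUE)))
}

# squared-distance matrix between gene copies: entry = number of loci at which
# the two copies carry different alleles, over loci typed in both carriers
copy_distance2 <- function(gt) {
  hap <- rbind(gt$a1, gt$a2)                   # 2N x L, copy c of ind i at (c-1)N+i
  n2 <- nrow(hap)
  D2 <- matrix(0, n2, n2)
  for (l in seq_len(ncol(hap))) {
    a <- hap[, l]
    dl <- outer(a, a, "!=")
    dl[is.na(dl)] <- 0
    D2 <- D2 + dl
  }
  D2
}

amova_components <- function(D2, unit_group) {
  groups <- unique(unit_group)
  N <- length(unit_group); G <- length(groups)
  SSt <- sum(D2) / (2 * N)                      # sum over unordered pairs / N
  SSw <- 0
  for (g in groups) {
    i <- unit_group == g
    SSw <- SSw + sum(D2[i, i]) / (2 * sum(i))
  }
  SSa <- SSt - SSw
  df_a <- G - 1L; df_w <- N - G
  MSa <- SSa / df_a; MSw <- SSw / df_w
  ng <- as.vector(table(unit_group))
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  s2w <- MSw
  s2a <- (MSa - MSw) / n0
  list(SSa = SSa, SSw = SSw, SSt = SSt, df = c(among = df_a, within = df_w,
       total = N - 1L), s2a = s2a, s2w = s2w,
       fst = s2a / (s2a + s2w))
}

#' Analysis of molecular variance (one level)
#'
#' Distance-based AMOVA on gene copies: each diploid individual contributes two
#' allele copies; the squared distance between two copies is the number of loci
#' (typed in both) at which they differ. Sums of squares follow the standard
#' squared-distance partition identities; variance components come from the
#' mean squares with the usual unequal-size weighting; F_ST is the among-group
#' fraction. The permutation test shuffles whole individuals among groups (both
#' copies move together); p is computed with the add-one rule so the observed
#' configuration counts in numerator and denominator.
#'
#' @param gt a [genotype_table()] (group labels define the grouping).
#' @param n_perm number of label permutations for the p-value (0 = skip).
#' @param seed optional RNG seed for the permutations.
#' @return object of class `amova_result`: df, sums of squares, variance
#'   components, percentage variation, `fst`, `p_value`, `n_perm`.
#' @export
amova <- function(gt, n_perm = 999, seed = NULL) {
  grp <- gt$group
  groups <- unique(grp)
  if (length(groups) < 2) stop("AMOVA needs >= 2 groups")
  if (any(table(grp) < 2)) warning("group of size 1 present")
  if (n_perm < 0) stop("n_perm must be >= 0")
  D2 <- copy_distance2(gt)
  unit_group <- c(grp, grp)                     # copies follow their individual
  obs <- amova_components(D2, unit_group)
  flag <- obs$s2a < 0
  if (flag) warning("negative among-group variance component (reported as-is)")
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(grp)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pg <- grp[sample.int(n)]
      if (amova_components(D2, c(pg, pg))$fst >= obs$fst) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(df = obs$df,
                 SS = c(among = obs$SSa, within = obs$SSw, total = obs$SSt),
                 sigma2 = c(among = obs$s2a, within = obs$s2w),
                 percent = amova_percentages(obs$s2a, obs$s2w),
                 fst = obs$fst, p_value = p, n_perm = n_perm,
                 negative_component = flag),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (gene copies as units; df among = groups - 1)\n")
  tab <- data.frame(df = x$df[1:2], SS = x$SS[1:2], sigma2 = x$sigma2,
                    percent = x$percent)
  print(round(tab, 5))
  cat("F_ST =", format(x$fst, digits = 5))
  if (!is.na(x$p_value)) cat("  (p =", format(x$p_value, digits = 3),
                             "from", x$n_perm, "permutations)")
  cat("\n")
  invisible(x)
}

#' Pairwise F_ST matrix between groups
#'
#' Two-group AMOVA ([amova()]) applied to every group pair.
#'
#' @param gt a [genotype_table()].
#' @param n_perm permutations per pair for p-values (0 = skip).
#' @param seed optional RNG seed.
#' @return list with symmetric matrix `fst` (zero diagonal) and, when
#'   permutations were run, matrix `p`.
#' @export
pairwise_fst <- function(gt, n_perm = 0, seed = NULL) {
  groups <- sort(unique(gt$group))
  G <- length(groups)
  if (G < 2) stop("pairwise F_ST needs >= 2 groups")
  fst <- matrix(0, G, G, dimnames = list(groups, groups))
  pm <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    sub <- gt[gt$group %in% groups[c(i, j)]]
    res <- suppressWarnings(amova(sub, n_perm = n_perm))
    fst[i, j] <- fst[j, i] <- res$fst
    pm[i, j] <- pm[j, i] <- res$p_value
  }
  list(fst = fst, p = if (n_perm > 0) pm else NULL)
}

#' Contingency chi-square test of allele-frequency heterogeneity
#'
#' Per locus, the standard contingency statistic on the groups x alleles
#' copy-count table; expected counts from the margins; alleles with zero
#' margin dropped; df = (groups - 1)(alleles - 1).
#'
#' @param ac an `allele_counts` object with >= 2 groups.
#' @return data.frame with columns `locus`, `chi2`, `df`, `p`.
#' @export
chi2_heterogeneity <- function(ac) {
  if (length(ac$groups) < 2) stop("heterogeneity test needs >= 2 groups")
  out <- lapply(seq_along(ac$loci), function(l) {
    m <- ac$counts[[l]]
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    chi2 <- sum((m - E)^2 / E)
    df <- (nrow(m) - 1L) * (ncol(m) - 1L)
    data.frame(locus = ac$loci[l], chi2 = chi2, df = df,
               p = pchisq(chi2, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
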