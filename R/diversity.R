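#' Fixation index from heterozygosities
#'
#' F = 1 - Ho/He, the heterozygote deficit relative to Hardy-Weinberg
#' expectation. Undefined (NA) when He = 0 (monomorphic locus).
#'
#' @param he,ho expected and observed heterozygosity in [0, 1].
#' @return numeric vector of fixation indices.
#' @export
fixation_index <- function(he, ho) ifelse(he > 0, 1 - ho / he, NA_real_)

gene_diversity <- function(p) 1 - sum(p^2)

#' Per-locus diversity statistics
#'
#' For each locus over the pooled sample: typed sample size n, observed allele
#' count A, expected heterozygosity (gene diversity) He = 1 - sum p_a^2,
#' observed heterozygosity Ho (fraction of typed individuals heterozygous) and
#' fixation index F = 1 - Ho/He. Column means are unweighted across loci. The
#' mean fixation index is ambiguous in published tables (column mean vs.
#' recomputed from mean He/Ho); both are returned in the `"means"` attribute.
#'
#' @param gt a [genotype_table()].
#' @param unbiased apply the small-sample correction N/(N-1) to He.
#' @return data.frame with columns `locus`, `n`, `A`, `He`, `Ho`, `F`;
#'   attribute `"means"` holds the unweighted column means plus
#'   `F_from_means = 1 - mean(Ho)/mean(He)`.
#' @export
locus_diversity <- function(gt, unbiased = FALSE) {
  ac <- allele_counts(gt, by_group = FALSE)
  L <- length(gt$loci)
  n <- A <- He <- Ho <- numeric(L)
  for (l in seq_len(L)) {
    cts <- ac$counts[[l]][1, ]
    N <- sum(cts)
    if (N == 0) stop("locus with no typed accessions: ", gt$loci[l])
    p <- cts / N
    n[l] <- ac$n_typed[1, l]
    A[l] <- sum(cts > 0)
    He[l] <- gene_diversity(p)
    if (unbiased) He[l] <- He[l] * N / (N - 1)
    typed <- !is.na(gt$a1[, l])
    Ho[l] <- mean(gt$a1[typed, l] != gt$a2[typed, l])
  }
  F <- fixation_index(He, Ho)
  out <- data.frame(locus = gt$loci, n = n, A = A, He = He, Ho = Ho, F = F,
                    stringsAsFactors = FALSE)
  attr(out, "means") <- c(n = mean(n), A = mean(A), He = mean(He),
                          Ho = mean(Ho), F = mean(F, na.rm = TRUE),
                          F_from_means = 1 - mean(Ho) / mean(He))
  out
}

# P(allele with N_a copies out of N appears in a subsample of g copies),
# exact hypergeometric complement via log-gamma for stability
rarefied_q <- function(Na, N, g) {
  q <- numeric(length(Na))
  can_miss <- N - Na >= g
  q[!can_miss] <- 1
  q[can_miss] <- 1 - exp(lchoose(N - Na[can_miss], g) - lchoose(N, g))
  q
}

check_g <- function(ac, g) {
  N <- 2L * ac$n_typed
  if (length(g) != 1L || g < 2) stop("g must be a single count >= 2")
  if (any(N < g)) {
    bad <- which(N < g, arr.ind = TRUE)[1, ]
    stop("g = ", g, " exceeds gene copies (", N[bad[1], bad[2]], ") for group '",
         ac$groups[bad[1]], "' at locus '", ac$loci[bad[2]], "'")
  }
}

#' Default rarefaction size: smallest gene-copy count over groups and loci
#' @param ac an `allele_counts` object.
#' @return integer number of gene copies.
#' @export
default_rarefaction_g <- function(ac) as.integer(min(2L * ac$n_typed))

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: Ar = sum_a [1 - C(N - N_a, g) / C(N, g)], computed exactly with
#' log-gamma binomial coefficients (no simulation). Standardizing all groups
#' to one `g` makes richness comparable despite unequal sample sizes.
#'
#' @param ac an `allele_counts` object (usually by group).
#' @param g gene-copy count; must be >= 2 and <= every group x locus copy
#'   count. Default: [default_rarefaction_g()].
#' @return groups x loci matrix of Ar; attribute `"group_means"` holds the
#'   unweighted per-group mean over loci.
#' @export
rarefied_allelic_richness <- function(ac, g = default_rarefaction_g(ac)) {
  check_g(ac, g)
  ar <- matrix(NA_real_, length(ac$groups), length(ac$loci),
               dimnames = list(ac$groups, ac$loci))
  for (l in seq_along(ac$loci)) {
    m <- ac$counts[[l]]
    for (gi in seq_along(ac$groups)) {
      cts <- m[gi, ]; cts <- cts[cts > 0]
      ar[gi, l] <- sum(rarefied_q(cts, sum(m[gi, ]), g))
    }
  }
  attr(ar, "group_means") <- rowMeans(ar)
  ar
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles present in a `g`-copy subsample of the focal
#' group and absent from independent `g`-copy subsamples of every other group:
#' PAr = sum_a Q_g^focal(a) * prod_{j != focal} (1 - Q_g^j(a)), with
#' Q_g^j(a) = 1 - C(N_j - N_ja, g)/C(N_j, g).
#'
#' @inheritParams rarefied_allelic_richness
#' @return groups x loci matrix of PAr; attribute `"group_means"`.
#' @export
private_rarefied_richness <- function(ac, g = default_rarefaction_g(ac)) {
  if (length(ac$groups) < 2) stop("private richness needs >= 2 groups")
  check_g(ac, g)
  par <- matrix(NA_real_, length(ac$groups), length(ac$loci),
                dimnames = list(ac$groups, ac$loci))
  for (l in seq_along(ac$loci)) {
    m <- ac$counts[[l]]
    N <- rowSums(m)
    Q <- vapply(seq_along(ac$groups),
                function(gi) rarefied_q(m[gi, ], N[gi], g),
                numeric(ncol(m)))          # alleles x groups
    Q <- matrix(Q, ncol = length(ac$groups))
    for (gi in seq_along(ac$groups)) {
      other <- Q[, -gi, drop = FALSE]
      par[gi, l] <- sum(Q[, gi] * apply(1 - other, 1, prod))
    }
  }
  attr(par, "group_means") <- rowMeans(par)
  par
}

#' Inventory of private alleles
#'
#' An allele is private iff its copy count is positive in exactly one group.
#'
#' @param ac an `allele_counts` object with >= 2 groups.
#' @return list with `alleles` (per group, character vector `locus.allele`) and
#'   `n` (named count per group, plus attribute `"total"`).
#' @export
private_allele_inventory <- function(ac) {
  if (length(ac$groups) < 2) stop("private alleles need >= 2 groups")
  priv <- setNames(vector("list", length(ac$groups)), ac$groups)
  for (l in seq_along(ac$loci)) {
    m <- ac$counts[[l]]
    present <- m > 0
    one <- colSums(present) == 1L
    if (any(one)) {
      owner <- apply(present[, one, drop = FALSE], 2, which)
      for (k in seq_along(owner)) {
        gname <- ac$groups[owner[k]]
        priv[[gname]] <- c(priv[[gname]],
                           paste(ac$loci[l], colnames(m)[one][k], sep = "."))
      }
    }
  }
  n <- vapply(priv, length, 0L)
  attr(n, "total") <- sum(n)
  list(alleles = priv, n = n)
}

#' Per-group diversity summary
#'
#' Group-level analogue of a within-population variability table: mean typed
#' sample size n, mean alleles per locus A, rarefied allelic richness Ar and
#' private allelic richness PAr at `g` gene copies, mean He and Ho over loci,
#' fixation index F = 1 - mean(Ho)/mean(He), and the total allele count.
#'
#' @param gt a [genotype_table()].
#' @param g rarefaction gene-copy count (default: smallest group x locus count).
#' @return data.frame, one row per group plus an unweighted `Mean` row.
#' @export
group_diversity <- function(gt, g = NULL) {
  ac <- allele_counts(gt, by_group = TRUE)
  if (is.null(g)) g <- default_rarefaction_g(ac)
  ar <- rarefied_allelic_richness(ac, g)
  par <- private_rarefied_richness(ac, g)
  G <- length(ac$groups); L <- length(ac$loci)
  n <- rowMeans(ac$n_typed)
  A_mat <- vapply(ac$counts, function(m) rowSums(m > 0), numeric(G))
  A_mat <- matrix(A_mat, nrow = G)
  he <- ho <- matrix(NA_real_, G, L)
  for (l in seq_len(L)) {
    m <- ac$counts[[l]]
    for (gi in seq_len(G)) {
      he[gi, l] <- gene_diversity(m[gi, ] / sum(m[gi, ]))
      sel <- !is.na(gt$a1[, l]) & gt$group == ac$groups[gi]
      ho[gi, l] <- mean(gt$a1[sel, l] != gt$a2[sel, l])
    }
  }
  out <- data.frame(group = ac$groups, n = n, A = rowMeans(A_mat),
                    Ar = rowMeans(ar), PAr = rowMeans(par),
                    He = rowMeans(he), Ho = rowMeans(ho),
                    F = fixation_index(rowMeans(he), rowMeans(ho)),
                    total_alleles = rowSums(A_mat), stringsAsFactors = FALSE)
  means <- c(list(group = "Mean"), lapply(out[-1], mean))
  out <- rbind(out, as.data.frame(means, stringsAsFactors = FALSE))
  attr(out, "g") <- g
  out
}

#' Write a table as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
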