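#' Shared-allele distance between accessions
#'
#' For each pair, over loci typed in both accessions: the shared count at a
#' locus is the size of the multiset intersection of the two allele pairs
#' (0, 1 or 2); the distance is 1 - sum(shared) / (2 * loci compared). Pairs
#' with no jointly typed locus get `NA` with a warning.
#'
#' @param gt a [genotype_table()].
#' @return symmetric matrix in [0, 1] with zero diagonal; attribute
#'   `"n_loci"` counts loci compared per pair.
#' @export
shared_allele_distance <- function(gt) {
  n <- length(gt$id)
  labs <- locus_allele_labels(gt)
  shared <- matrix(0, n, n)
  nloc <- matrix(0L, n, n)
  for (l in seq_along(gt$loci)) {
    typed <- !is.na(gt$a1[, l])
    idx <- which(typed)
    if (length(idx) < 2) next
    A <- length(labs[[l]])
    dos <- matrix(0L, length(idx), A)
    i1 <- match(gt$a1[idx, l], labs[[l]]); i2 <- match(gt$a2[idx, l], labs[[l]])
    dos[cbind(seq_along(idx), i1)] <- dos[cbind(seq_along(idx), i1)] + 1L
    dos[cbind(seq_along(idx), i2)] <- dos[cbind(seq_along(idx), i2)] + 1L
    l1 <- matrix(0, length(idx), length(idx))
    for (a in seq_len(A)) l1 <- l1 + abs(outer(dos[, a], dos[, a], "-"))
    shared[idx, idx] <- shared[idx, idx] + (2 - l1 / 2)
    nloc[idx, idx] <- nloc[idx, idx] + 1L
  }
  d <- 1 - shared / (2 * nloc)
  diag(d) <- 0
  if (any(nloc[upper.tri(nloc)] == 0)) {
    warning("accession pair(s) share no typed locus; distance set to NA")
    d[nloc == 0] <- NA_real_
  }
  dimnames(d) <- list(gt$id, gt$id)
  attr(d, "n_loci") <- nloc
  d
}

#' Nei & Li distance on a binary presence matrix
#'
#' d = 1 - 2 n_xy / (n_x + n_y): one minus the Dice coefficient on allele
#' presences.
#'
#' @param bm 0/1 matrix from [binary_presence_matrix()].
#' @return symmetric matrix in [0, 1], zero diagonal.
#' @export
nei_li_distance <- function(bm) {
  rs <- rowSums(bm)
  if (any(rs == 0)) stop("accession with no allele presences: ",
                         paste(rownames(bm)[rs == 0], collapse = ", "))
  shared <- bm %*% t(bm)
  d <- 1 - 2 * shared / outer(rs, rs, "+")
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (delegated to \pkg{ape}); exactly recovers the
#' generating topology and branch lengths for additive distances. Negative
#' branch lengths are reported as-is with a warning.
#'
#' @param dm complete symmetric distance matrix over >= 3 taxa.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("NJ needs >= 3 taxa")
  if (anyNA(dm)) stop("distance matrix has missing entries")
  tr <- ape::nj(as.dist(dm))
  if (any(tr$edge.length < -1e-12)) warning("NJ produced negative branch lengths")
  tr
}

#' Locus-bootstrap support for a neighbor-joining tree
#'
#' Loci are the exchangeable units: each replicate resamples loci with
#' replacement, rebuilds the distance matrix and NJ tree, and the support of
#' each internal edge of the reference tree is the percentage of replicates
#' whose tree contains the same bipartition.
#'
#' @param gt a [genotype_table()] with >= 2 loci.
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed optional RNG seed.
#' @param distance `"shared_allele"` (genotype input) or `"nei_li"` (binary).
#' @return the reference `phylo` tree with supports (0-100) in `node.label`.
#' @export
bootstrap_support <- function(gt, n_reps = 100, seed = NULL,
                              distance = c("shared_allele", "nei_li")) {
  distance <- match.arg(distance)
  if (length(gt$loci) < 2) stop("bootstrap needs >= 2 loci")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dfun <- function(x) {
    if (distance == "shared_allele") shared_allele_distance(x)
    else nei_li_distance(binary_presence_matrix(x))
  }
  resample_loci <- function(x, li) {
    genotype_table(x$a1[, li, drop = FALSE], x$a2[, li, drop = FALSE],
                   id = x$id, group = x$group,
                   loci = paste0(x$loci[li], ".", seq_along(li)),
                   lon = x$lon, lat = x$lat)
  }
  ref <- neighbor_joining(dfun(gt))
  L <- length(gt$loci)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    li <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- suppressWarnings(neighbor_joining(dfun(resample_loci(gt, li))))
  }
  class(boots) <- "multiPhylo"
  cnt <- ape::prop.clades(ref, part = ape::prop.part(boots), rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  ref$node.label <- round(100 * cnt / n_reps, 1)
  ref
}

#' PCA of the genotype dosage matrix
#'
#' Column-centered, unscaled principal components; missing calls were
#' mean-imputed upstream so imputed cells sit at the column center.
#'
#' @param dm dosage matrix from [dosage_matrix()].
#' @param n_axes number of axes to return scores for.
#' @return list with `scores` (accessions x axes) and `var_frac` (fraction of
#'   total variance per axis, non-increasing).
#' @export
pca_genotypes <- function(dm, n_axes = min(10L, nrow(dm) - 1L)) {
  if (nrow(dm) < 2) stop("PCA needs >= 2 accessions")
  keep <- apply(dm, 2, function(x) var(x) > 0)
  if (!any(keep)) stop("constant dosage matrix")
  pc <- prcomp(dm[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  n_axes <- min(n_axes, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_axes), drop = FALSE],
       var_frac = vf)
}

#' Write a tree in Newick format (supports as internal node labels)
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
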