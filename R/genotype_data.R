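#' Diploid multilocus genotype table
#'
#' Container for codominant (microsatellite) genotypes: one row per accession,
#' two integer allele codes per locus, a group label per accession and optional
#' longitude/latitude. Allele pairs are unordered; they are stored canonically
#' with `a1 <= a2`. A call is either fully typed or fully missing (`NA` in both
#' slots); a half-missing call is promoted to fully missing.
#'
#' @param a1,a2 integer matrices (accessions x loci) of allele codes, `NA` for
#'   missing calls. Allele codes must be positive integers (fragment sizes are
#'   treated as opaque labels; no binning is applied).
#' @param id character vector of unique accession identifiers.
#' @param group character vector of group labels (e.g. geographic regions).
#' @param loci character vector of locus names.
#' @param lon,lat optional numeric vectors of decimal-degree coordinates.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, id, group, loci = colnames(a1),
                           lon = NULL, lat = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 must have identical dimensions")
  n <- nrow(a1)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (length(id) != n) stop("id length must equal the number of accessions")
  if (anyDuplicated(id)) stop("duplicate accession ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(group) != n) stop("group length must equal the number of accessions")
  if (any(a1 < 1L, na.rm = TRUE) || any(a2 < 1L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  # promote half-missing to fully missing; canonical order a1 <= a2
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(id, loci)
  structure(list(id = as.character(id), group = as.character(group),
                 loci = as.character(loci), a1 = a1, a2 = a2,
                 lon = lon, lat = lat),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$id), "accessions,", length(x$loci), "loci,",
      length(unique(x$group)), "groups;",
      sum(is.na(x$a1)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$id), length(x$loci))

#' Subset accessions of a genotype table
#' @param x a `genotype_table`.
#' @param i accession index (logical, integer or id).
#' @param ... unused.
#' @export
`[.genotype_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  genotype_table(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                 id = x$id[i], group = x$group[i], loci = x$loci,
                 lon = x$lon[i], lat = x$lat[i])
}

#' Read a genotype table from a delimited file
#'
#' Expected layout: a header row; an `id` column, a `group` column, optional
#' `lon`/`lat` columns, then either two columns per locus (names `X` and
#' `X_2`/`X.1`, or any pair of columns sharing a stem) or one column per locus
#' holding `"a/b"` calls. The declared missing code (default `"0"`, empty cells
#' also count) marks untyped calls; a half-missing call becomes fully missing.
#'
#' @param path file path; comma- or tab-delimited (sniffed from the header).
#' @param missing_code character scalar coding a missing allele.
#' @return A [genotype_table()]. The per-locus missing-call counts are attached
#'   as attribute `"n_missing"`.
#' @export
read_genotype_table <- function(path, missing_code = "0") {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, strip.white = TRUE)
  if (!all(c("id", "group") %in% names(df)))
    stop("genotype file must have 'id' and 'group' columns")
  meta <- intersect(c("id", "group", "lon", "lat"), names(df))
  gcols <- setdiff(names(df), meta)
  if (!length(gcols)) stop("no locus columns found")
  n <- nrow(df)
  parse_allele <- function(v) {
    v[v == "" | v == missing_code] <- NA_character_
    bad <- !is.na(v) & !grepl("^[0-9]+$", v)
    if (any(bad)) stop("non-integer allele codes: ", paste(unique(v[bad]), collapse = ", "))
    as.integer(v)
  }
  if (any(grepl("/", unlist(df[gcols][1, ], use.names = FALSE), fixed = TRUE))) {
    loci <- gcols
    a1 <- a2 <- matrix(NA_integer_, n, length(loci))
    for (j in seq_along(loci)) {
      parts <- strsplit(df[[loci[j]]], "/", fixed = TRUE)
      bad <- lengths(parts) != 2L & !(df[[loci[j]]] %in% c("", missing_code))
      if (any(bad)) stop("ragged genotype entries at locus ", loci[j])
      a1[, j] <- parse_allele(vapply(parts, function(p) if (length(p) == 2) p[1] else NA_character_, ""))
      a2[, j] <- parse_allele(vapply(parts, function(p) if (length(p) == 2) p[2] else NA_character_, ""))
    }
  } else {
    if (length(gcols) %% 2L != 0L)
      stop("expected two columns per locus, got an odd number (", length(gcols), ")")
    j1 <- gcols[seq(1, length(gcols), by = 2)]
    loci <- sub("[._ ]?[12aAbB]$", "", j1)
    a1 <- vapply(gcols[seq(1, length(gcols), by = 2)], function(cn) parse_allele(df[[cn]]), integer(n))
    a2 <- vapply(gcols[seq(2, length(gcols), by = 2)], function(cn) parse_allele(df[[cn]]), integer(n))
    a1 <- matrix(a1, n); a2 <- matrix(a2, n)
  }
  gt <- genotype_table(a1, a2, id = df$id, group = df$group, loci = loci,
                       lon = if ("lon" %in% meta) as.numeric(df$lon),
                       lat = if ("lat" %in% meta) as.numeric(df$lat))
  attr(gt, "n_missing") <- colSums(is.na(gt$a1))
  gt
}

#' Write a genotype table as CSV (two columns per locus)
#' @param gt a `genotype_table`.
#' @param path output path.
#' @param missing_code code written for missing alleles.
#' @export
write_genotype_table <- function(gt, path, missing_code = "0") {
  enc <- function(m) { m <- matrix(as.character(m), nrow(m)); m[is.na(m)] <- missing_code; m }
  a1 <- enc(gt$a1); a2 <- enc(gt$a2)
  out <- data.frame(id = gt$id, group = gt$group, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(gt$lon)) { out$lon <- gt$lon; out$lat <- gt$lat }
  for (j in seq_along(gt$loci)) {
    out[[paste0(gt$loci[j], "_1")]] <- a1[, j]
    out[[paste0(gt$loci[j], "_2")]] <- a2[, j]
  }
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GenePop-format genotype file
#'
#' Standard GenePop dialect: a title line, locus names (one per line, or one
#' comma-separated line), `Pop` markers starting each population, and per
#' individual `id ,  aaabbb aaabbb ...` rows with 2- or 3-digit allele codes
#' (`00`/`000` = missing). Population order defines group labels `pop1..popG`.
#'
#' @param path file path.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  pops <- grep("^pop$", ln, ignore.case = TRUE)
  if (!length(pops)) stop("no 'Pop' marker found")
  hdr <- ln[2:(pops[1] - 1)]
  loci <- unlist(strsplit(hdr, ",\\s*"))
  ids <- character(); grp <- character(); rows <- list()
  bounds <- c(pops, length(ln) + 1L)
  for (p in seq_along(pops)) {
    for (i in (bounds[p] + 1L):(bounds[p + 1L] - 1L)) {
      parts <- strsplit(ln[i], ",")[[1]]
      if (length(parts) < 2) stop("malformed GenePop row: ", ln[i])
      ids <- c(ids, trimws(parts[1])); grp <- c(grp, paste0("pop", p))
      calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(calls) != length(loci))
        stop("row has ", length(calls), " loci, expected ", length(loci))
      rows[[length(rows) + 1L]] <- calls
    }
  }
  w <- nchar(rows[[1]][1]) / 2L
  if (!w %in% c(2L, 3L)) stop("allele codes must be 2 or 3 digits")
  a1 <- t(vapply(rows, function(r) as.integer(substr(r, 1, w)), integer(length(loci))))
  a2 <- t(vapply(rows, function(r) as.integer(substr(r, w + 1, 2 * w)), integer(length(loci))))
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_table(a1, a2, id = ids, group = grp, loci = loci)
}

#' Gene-copy counts per group, locus and allele
#'
#' Tabulates allele copies: for each group g and locus l a vector of counts
#' N_gla over observed alleles, with N_gl = sum_a N_gla = 2 * n_gl where n_gl
#' is the number of fully typed individuals. These counts are the basis for
#' every diversity and differentiation statistic in the package.
#'
#' @param gt a [genotype_table()].
#' @param by_group if `FALSE`, all accessions are pooled into one group `"all"`.
#' @return An object of class `allele_counts`: a list with `counts` (per locus,
#'   a groups x alleles integer matrix), `n_typed` (groups x loci), `groups`,
#'   `loci`.
#' @export
allele_counts <- function(gt, by_group = TRUE) {
  groups <- if (by_group) sort(unique(gt$group)) else "all"
  gl <- if (by_group) gt$group else rep("all", length(gt$id))
  if (by_group && any(!table(factor(gl, groups)))) stop("empty group")
  L <- length(gt$loci)
  counts <- vector("list", L); names(counts) <- gt$loci
  n_typed <- matrix(0L, length(groups), L, dimnames = list(groups, gt$loci))
  for (l in seq_len(L)) {
    typed <- !is.na(gt$a1[, l])
    alleles <- sort(unique(c(gt$a1[typed, l], gt$a2[typed, l])))
    m <- matrix(0L, length(groups), length(alleles),
                dimnames = list(groups, as.character(alleles)))
    for (g in seq_along(groups)) {
      sel <- typed & gl == groups[g]
      m[g, ] <- tabulate(match(c(gt$a1[sel, l], gt$a2[sel, l]), alleles),
                         nbins = length(alleles))
      n_typed[g, l] <- sum(sel)
    }
    counts[[l]] <- m
  }
  structure(list(counts = counts, n_typed = n_typed, groups = groups,
                 loci = gt$loci), class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("allele_counts:", length(x$groups), "group(s),", length(x$loci),
      "loci,", sum(vapply(x$counts, ncol, 0L)), "alleles total\n")
  invisible(x)
}

#' Pool an allele_counts object across groups
#' @param ac an `allele_counts` object.
#' @return An `allele_counts` with a single group `"all"`.
#' @export
pool_counts <- function(ac) {
  counts <- lapply(ac$counts, function(m) {
    p <- matrix(colSums(m), 1L, dimnames = list("all", colnames(m)))
    storage.mode(p) <- "integer"; p
  })
  structure(list(counts = counts,
                 n_typed = matrix(colSums(ac$n_typed), 1L,
                                  dimnames = list("all", ac$loci)),
                 groups = "all", loci = ac$loci), class = "allele_counts")
}

locus_allele_labels <- function(gt) {
  labs <- lapply(seq_along(gt$loci), function(l) {
    typed <- !is.na(gt$a1[, l])
    sort(unique(c(gt$a1[typed, l], gt$a2[typed, l])))
  })
  names(labs) <- gt$loci
  labs
}

#' Accessions x (locus, allele) presence/absence matrix
#'
#' Entry 1 iff the allele is present in the accession's genotype at that locus.
#' A missing call yields all-zero columns for the locus; which entries were
#' untyped is recorded in the `"untyped"` attribute (accessions x loci).
#'
#' @param gt a [genotype_table()].
#' @return 0/1 matrix with columns named `locus.allele`; attributes `"locus"`
#'   (column -> locus name) and `"untyped"`.
#' @export
binary_presence_matrix <- function(gt) {
  labs <- locus_allele_labels(gt)
  if (any(!lengths(labs))) stop("locus with zero typed accessions: ",
                                paste(gt$loci[!lengths(labs)], collapse = ", "))
  n <- length(gt$id)
  cols <- unlist(lapply(seq_along(labs), function(l)
    paste(gt$loci[l], labs[[l]], sep = ".")))
  bm <- matrix(0L, n, length(cols), dimnames = list(gt$id, cols))
  locus_of <- rep(gt$loci, lengths(labs))
  off <- c(0L, cumsum(lengths(labs)))
  for (l in seq_along(labs)) {
    i1 <- match(gt$a1[, l], labs[[l]]); i2 <- match(gt$a2[, l], labs[[l]])
    ok <- which(!is.na(i1))
    bm[cbind(ok, off[l] + i1[ok])] <- 1L
    bm[cbind(ok, off[l] + i2[ok])] <- 1L
  }
  attr(bm, "locus") <- locus_of
  attr(bm, "untyped") <- is.na(gt$a1)
  bm
}

#' Accessions x (locus, allele) dosage matrix with mean imputation
#'
#' Dosages in {0,1,2}; for typed loci a row sums to 2 over the locus's columns.
#' Missing calls are imputed with the column mean of the typed accessions so a
#' centered PCA stays well defined (imputed cells then sit exactly at the
#' center). A locus typed in no accession gets constant 0 columns and a warning.
#'
#' @param gt a [genotype_table()].
#' @param impute impute missing entries with column means (default `TRUE`;
#'   otherwise they stay `NA`).
#' @return numeric matrix; attributes `"locus"` and `"n_imputed"`.
#' @export
dosage_matrix <- function(gt, impute = TRUE) {
  labs <- locus_allele_labels(gt)
  if (any(!lengths(labs))) {
    warning("locus with zero typed accessions imputed as constant: ",
            paste(gt$loci[!lengths(labs)], collapse = ", "))
    labs[!lengths(labs)] <- list(1L)
  }
  n <- length(gt$id)
  cols <- unlist(lapply(seq_along(labs), function(l)
    paste(gt$loci[l], labs[[l]], sep = ".")))
  dm <- matrix(NA_real_, n, length(cols), dimnames = list(gt$id, cols))
  off <- c(0L, cumsum(lengths(labs)))
  for (l in seq_along(labs)) {
    jj <- (off[l] + 1L):off[l + 1L]
    d <- matrix(0, n, length(jj))
    i1 <- match(gt$a1[, l], labs[[l]]); i2 <- match(gt$a2[, l], labs[[l]])
    ok <- which(!is.na(i1))
    d[cbind(ok, i1[ok])] <- d[cbind(ok, i1[ok])] + 1
    d[cbind(ok, i2[ok])] <- d[cbind(ok, i2[ok])] + 1
    d[setdiff(seq_len(n), ok), ] <- NA_real_
    dm[, jj] <- d
  }
  n_imp <- sum(is.na(dm))
  if (impute && n_imp) {
    mu <- colMeans(dm, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(dm), arr.ind = TRUE)
    dm[idx] <- mu[idx[, 2]]
  }
  attr(dm, "locus") <- rep(gt$loci, lengths(labs))
  attr(dm, "n_imputed") <- n_imp
  dm
}
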