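#' Regular lon/lat grid raster
#'
#' Minimal native raster: a value matrix whose first row is the northernmost
#' row, the lower-left corner of the grid, a square cell size in decimal
#' degrees, and `NA` for nodata. Coordinates follow the cell-center convention;
#' point-in-cell assignment is half-open [west, east) x [south, north).
#'
#' @param values numeric matrix (row 1 = top/north).
#' @param xll,yll lower-left corner of the grid (degrees).
#' @param cellsize cell edge in decimal degrees.
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  values <- as.matrix(values)
  if (any(!is.finite(values) & !is.na(values))) stop("values must be finite or NA")
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("grid_raster:", nrow(x$values), "x", ncol(x$values), "cells of",
      x$cellsize, "deg; origin (", x$xll, ",", x$yll, ");",
      sum(is.na(x$values)), "nodata\n")
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

#' Cell-center coordinates of a grid raster
#' @param r a `grid_raster`.
#' @return list with `lon` (per column) and `lat` (per row, top first), and
#'   matrices `lon_mat`/`lat_mat` matching the value matrix.
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  lon <- r$xll + (seq_len(nc) - 0.5) * r$cellsize
  lat <- r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize
  list(lon = lon, lat = lat,
       lon_mat = matrix(lon, nr, nc, byrow = TRUE),
       lat_mat = matrix(lat, nr, nc))
}

#' Row/column of the cell containing points
#' @param r a `grid_raster`.
#' @param lon,lat point coordinates.
#' @return two-column matrix (row, col); NA for points off the grid.
#' @export
cell_of <- function(r, lon, lat) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((lon - r$xll) / r$cellsize) + 1L
  row_b <- floor((lat - r$yll) / r$cellsize) + 1L
  row <- nr - row_b + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Read / write an ESRI ASCII grid
#' @param path file path.
#' @return a [grid_raster()].
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  nd <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  m <- as.matrix(read.table(path, skip = length(hdr)))
  dimnames(m) <- NULL
  m[m == nd] <- NA_real_
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]] else vals[["xllcenter"]] - vals[["cellsize"]] / 2
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]] else vals[["yllcenter"]] - vals[["cellsize"]] / 2
  grid_raster(m, xll, yll, vals[["cellsize"]])
}

#' @rdname read_ascii_grid
#' @param r a `grid_raster`.
#' @param nodata sentinel written for NA cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  m <- r$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", r$xll), paste("yllcorner", r$yll),
               paste("cellsize", r$cellsize), paste("NODATA_value", nodata)), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Great-circle (haversine) distance in km
#'
#' Sphere of radius 6371 km; vectorized over points.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  R <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

occ_frame <- function(occ) {
  if (!all(c("lon", "lat") %in% names(occ))) stop("occurrences need lon and lat columns")
  if (is.null(occ$id)) occ$id <- seq_len(nrow(occ))
  if (any(occ$lat < -90 | occ$lat > 90 | occ$lon < -180 | occ$lon > 180))
    stop("coordinates out of range")
  occ
}

#' Spatially rarefy (thin) occurrence records
#'
#' Exact coordinate duplicates are removed first (earliest record kept). Then,
#' while any retained pair is closer than `r_km`, the record with the most
#' neighbors within `r_km` is deleted; ties go to the lowest record index.
#' The result is an independent set at radius `r_km` and re-running it is a
#' no-op.
#'
#' @param occ data.frame with `id`, `lon`, `lat`.
#' @param r_km minimum allowed pair distance in km (> 0).
#' @return the thinned data.frame (original row order preserved).
#' @export
spatial_rarefy <- function(occ, r_km) {
  occ <- occ_frame(occ)
  if (!nrow(occ)) stop("empty occurrence set")
  if (r_km <= 0) stop("r_km must be positive")
  occ <- occ[!duplicated(occ[, c("lon", "lat")]), , drop = FALSE]
  n <- nrow(occ)
  if (n == 1) return(occ)
  D <- outer(seq_len(n), seq_len(n), function(i, j)
    great_circle_km(occ$lon[i], occ$lat[i], occ$lon[j], occ$lat[j]))
  close <- D < r_km
  diag(close) <- FALSE
  keep <- rep(TRUE, n)
  repeat {
    nn <- rowSums(close[, keep, drop = FALSE]) * keep
    if (all(nn == 0)) break
    drop <- which(nn == max(nn))[1]             # ties -> lowest index
    keep[drop] <- FALSE
    close[drop, ] <- FALSE; close[, drop] <- FALSE
  }
  occ[keep, , drop = FALSE]
}

#' Gaussian kernel-density sampling-bias grid
#'
#' Sum of isotropic Gaussian kernels (great-circle distances) over occurrence
#' points, evaluated at valid cell centers and linearly rescaled so the
#' minimum is exactly 1 and the maximum `max_bias`. Values of 1 mean no
#' detectable sampling bias; larger values mean denser sampling effort.
#'
#' @param occ data.frame with `lon`, `lat`.
#' @param template `grid_raster` defining grid and nodata cells.
#' @param bandwidth_km kernel s.d. in km; default = mean nearest-neighbor
#'   distance of the occurrences.
#' @param max_bias rescaled maximum (> 1).
#' @return a `grid_raster` of bias values.
#' @export
gaussian_bias_grid <- function(occ, template, bandwidth_km = NULL, max_bias = 10) {
  occ <- occ_frame(occ)
  valid <- which(!is.na(template$values))
  if (!length(valid)) stop("template has no valid cells")
  if (is.null(bandwidth_km)) {
    D <- outer(seq_len(nrow(occ)), seq_len(nrow(occ)), function(i, j)
      great_circle_km(occ$lon[i], occ$lat[i], occ$lon[j], occ$lat[j]))
    diag(D) <- Inf
    bandwidth_km <- mean(apply(D, 1, min))
  }
  if (bandwidth_km <= 0) stop("bandwidth must be positive")
  cc <- cell_centers(template)
  v <- template$values
  dens <- numeric(length(valid))
  for (p in seq_len(nrow(occ))) {
    d <- great_circle_km(cc$lon_mat[valid], cc$lat_mat[valid],
                         occ$lon[p], occ$lat[p])
    dens <- dens + exp(-d^2 / (2 * bandwidth_km^2))
  }
  rng <- range(dens)
  scaled <- if (rng[2] > rng[1])
    1 + (dens - rng[1]) / (rng[2] - rng[1]) * (max_bias - 1) else rep(1, length(dens))
  v[] <- NA_real_
  v[valid] <- scaled
  grid_raster(v, template$xll, template$yll, template$cellsize)
}

#' Inverse-distance-weighted interpolation surface
#'
#' Weights d^(-power) over great-circle distances; a cell whose center
#' coincides with a data point takes that point's value exactly. The surface
#' is bounded by the range of the input values.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param values numeric vector, one per point.
#' @param template `grid_raster` defining the output grid.
#' @param power IDW exponent.
#' @return a `grid_raster`.
#' @export
idw_surface <- function(points, values, template, power = 2) {
  points <- occ_frame(points)
  if (nrow(points) != length(values)) stop("one value per point required")
  valid <- which(!is.na(template$values))
  cc <- cell_centers(template)
  D <- vapply(seq_len(nrow(points)), function(p)
    great_circle_km(cc$lon_mat[valid], cc$lat_mat[valid],
                    points$lon[p], points$lat[p]),
    numeric(length(valid)))
  D <- matrix(D, length(valid))
  out <- numeric(length(valid))
  zero <- D == 0
  hit <- rowSums(zero) > 0
  out[hit] <- values[apply(zero[hit, , drop = FALSE], 1, which.max)]
  if (any(!hit)) {
    W <- D[!hit, , drop = FALSE]^(-power)
    out[!hit] <- as.vector(W %*% values) / rowSums(W)
  }
  v <- template$values
  v[] <- NA_real_
  v[valid] <- out
  grid_raster(v, template$xll, template$yll, template$cellsize)
}

#' Drop highly correlated covariate layers
#'
#' Pearson correlations are computed over jointly valid cells. While any pair
#' exceeds the threshold in |r|, the layer with the most offending partners is
#' dropped (tie: largest mean |r| against all remaining layers, then earliest
#' name). Constant layers (undefined r) are dropped first with a warning.
#'
#' @param stack named list of `grid_raster` layers on identical grids.
#' @param threshold |r| above which a pair counts as collinear.
#' @return character vector of retained layer names.
#' @export
correlation_prune <- function(stack, threshold = 0.7) {
  if (length(stack) < 2) stop("need >= 2 layers")
  if (is.null(names(stack))) names(stack) <- paste0("layer", seq_along(stack))
  for (s in stack[-1]) if (!same_grid(stack[[1]], s)) stop("layers on different grids")
  V <- vapply(stack, function(r) as.vector(r$values), numeric(length(stack[[1]]$values)))
  V <- V[stats::complete.cases(V), , drop = FALSE]
  const <- apply(V, 2, function(x) var(x) == 0)
  if (any(const)) {
    warning("dropping constant layer(s): ", paste(names(stack)[const], collapse = ", "))
    V <- V[, !const, drop = FALSE]
  }
  nm <- colnames(V)
  R <- abs(cor(V)); diag(R) <- 0
  while (any(R > threshold)) {
    deg <- rowSums(R > threshold)
    cand <- which(deg == max(deg))
    if (length(cand) > 1) cand <- cand[order(-rowMeans(R)[cand])][1]
    R <- R[-cand, -cand, drop = FALSE]
    nm <- nm[-cand]
  }
  nm
}
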