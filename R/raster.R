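## Gridded covariates on a regular planar grid. A vraster stores values[i, j]
## at cell centres x = x0 + (j-1) h, y = y0 + (i-1) h (row index i runs along
## y). All distances in km; covariate units are the layer's own.

#' Construct a gridded covariate layer
#'
#' @param values numeric R x C matrix; `values[i, j]` sits at the cell centre
#'   `(x0 + (j-1) h, y0 + (i-1) h)`. `NA` marks missing cells.
#' @param x0,y0 coordinates (km) of the centre of cell `[1, 1]`.
#' @param h cell size in km (> 0).
#' @param name layer name.
#' @return object of class `vraster`.
#' @export
vraster <- function(values, x0 = 0, y0 = 0, h = 1, name = "layer") {
  values <- as.matrix(values)
  if (h <= 0) stop("cell size h must be > 0")
  structure(list(name = name, x0 = x0, y0 = y0, h = h, values = values),
            class = "vraster")
}

#' @export
print.vraster <- function(x, ...) {
  cat("vraster '", x$name, "': ", nrow(x$values), " x ", ncol(x$values),
      " cells, h = ", x$h, " km, origin (", x$x0, ", ", x$y0, ")\n", sep = "")
  nm <- sum(is.na(x$values))
  if (nm > 0) cat("  ", nm, " missing cells\n")
  invisible(x)
}

raster_xcoords <- function(r) r$x0 + (seq_len(ncol(r$values)) - 1L) * r$h
raster_ycoords <- function(r) r$y0 + (seq_len(nrow(r$values)) - 1L) * r$h

same_geometry <- function(a, b) {
  isTRUE(all.equal(c(a$x0, a$y0, a$h, dim(a$values)),
                   c(b$x0, b$y0, b$h, dim(b$values))))
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file with the standard 6-line header.
#' @param name layer name (defaults to the file name).
#' @return a [vraster()].
#' @export
read_esri_ascii <- function(path, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      nhdr <- nhdr + 1L
    } else break
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (is.null(ncols) || is.null(nrows)) stop("malformed ESRI ASCII header in ", path)
  h <- hdr$cellsize
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = nhdr, quiet = TRUE)
  if (length(vals) != ncols * nrows) stop("raster body size mismatch in ", path)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[nrows:1, , drop = FALSE]          # file stores the top row first
  m[m == nodata] <- NA
  x0 <- (if (!is.null(hdr$xllcorner)) hdr$xllcorner + h / 2 else hdr$xllcenter)
  y0 <- (if (!is.null(hdr$yllcorner)) hdr$yllcorner + h / 2 else hdr$yllcenter)
  vraster(m, x0, y0, h, name = if (is.null(name)) basename(path) else name)
}

#' Write a [vraster()] as an ESRI ASCII grid
#' @param r a `vraster`.
#' @param path output `.asc` path.
#' @export
write_esri_ascii <- function(r, path) {
  stopifnot(inherits(r, "vraster"))
  m <- r$values
  m[is.na(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(r$x0 - r$h / 2, digits = 17)),
    paste("yllcorner", format(r$y0 - r$h / 2, digits = 17)),
    paste("cellsize", format(r$h, digits = 17)),
    "NODATA_value -9999"), con)
  for (i in nrow(m):1)
    writeLines(paste(format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' Fill missing raster cells by thin-plate interpolation
#'
#' Missing cells are replaced by an exact thin-plate radial-basis
#' interpolation (kernel \eqn{r^2 \log r} plus an affine polynomial) of the
#' observed cell centres; observed cells are returned unchanged. The
#' interpolant reproduces affine surfaces exactly. For large grids the spline
#' is fitted on a random subsample of observed cells.
#'
#' @param r a [vraster()] with at least 4 observed cells.
#' @param max_obs observed-cell cap for the dense solve (subsampled beyond it).
#' @param seed RNG seed for the subsample (only used when needed).
#' @return a `vraster` with no missing cells.
#' @export
fill_missing <- function(r, max_obs = 5000, seed = 1) {
  stopifnot(inherits(r, "vraster"))
  miss <- is.na(r$values)
  if (!any(miss)) return(r)
  obs <- which(!miss)
  if (length(obs) == 0L) stop("all cells missing in raster '", r$name, "'")
  if (length(obs) < 4L) stop("need at least 4 observed cells to interpolate")
  xs <- raster_xcoords(r); ys <- raster_ycoords(r)
  ij <- arrayInd(obs, dim(r$values))
  if (length(obs) > max_obs) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    pick <- sample(length(obs), max_obs)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    ij <- ij[pick, , drop = FALSE]
    obs <- obs[pick]
  }
  px <- xs[ij[, 2L]]; py <- ys[ij[, 1L]]
  z <- r$values[obs]
  n <- length(z)
  ## scale coordinates to O(1) for conditioning
  sc <- max(diff(range(px)), diff(range(py)), r$h)
  ux <- px / sc; uy <- py / sc
  d2 <- outer(ux, ux, "-")^2 + outer(uy, uy, "-")^2
  K <- ifelse(d2 > 0, 0.5 * d2 * log(d2), 0)   # r^2 log r with r^2 = d2
  P <- cbind(1, ux, uy)
  A <- rbind(cbind(K + diag(1e-10, n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(n)]; a <- sol[n + 1:3]
  mi <- which(miss)
  mij <- arrayInd(mi, dim(r$values))
  qx <- xs[mij[, 2L]] / sc; qy <- ys[mij[, 1L]] / sc
  d2q <- outer(qx, ux, "-")^2 + outer(qy, uy, "-")^2
  Kq <- ifelse(d2q > 0, 0.5 * d2q * log(d2q), 0)
  fill <- drop(Kq %*% w) + a[1L] + a[2L] * qx + a[3L] * qy
  out <- r
  out$values[mi] <- fill
  out
}

#' Blend two time slices of a covariate toward a reference time
#'
#' Cell-wise weighted mean of the slices bracketing `t_ref`, with weights
#' inversely proportional to the time gaps and normalized to sum to 1; an
#' exact endpoint receives weight 1.
#'
#' @param before,after `vraster`s on identical grids.
#' @param t_before,t_after,t_ref times (hours) with
#'   `t_before <= t_ref <= t_after`.
#' @return blended `vraster`.
#' @export
temporal_blend <- function(before, after, t_before, t_after, t_ref) {
  stopifnot(inherits(before, "vraster"), inherits(after, "vraster"))
  if (!same_geometry(before, after)) stop("temporal_blend: mismatched grids")
  if (t_ref < t_before || t_ref > t_after) stop("t_ref outside [t_before, t_after]")
  if (t_ref == t_before && t_ref == t_after) { w <- c(1, 0) }
  else if (t_ref == t_before) w <- c(1, 0)
  else if (t_ref == t_after) w <- c(0, 1)
  else {
    iw <- c(1 / (t_ref - t_before), 1 / (t_after - t_ref))
    w <- iw / sum(iw)
  }
  out <- before
  out$values <- w[1L] * before$values + w[2L] * after$values
  out$name <- paste0(before$name, "_blend")
  out
}

#' Euclidean distance covariate
#'
#' Builds a layer whose cells hold the Euclidean distance (km) from each cell
#' centre to a target point, or to the nearest `TRUE` cell of a mask on the
#' same grid. The gradient of such a layer points directly away from the
#' target, so it serves as a potential (gradient) covariate for attraction to
#' or repulsion from a site such as a rookery, or to the nearest cell of a
#' categorical cover type.
#'
#' @param geom a `vraster` supplying the grid geometry (values ignored unless
#'   `target` is a mask).
#' @param target either a numeric `c(x, y)` point (km) or a logical R x C mask.
#' @param name layer name.
#' @return a `vraster` of distances.
#' @export
distance_covariate <- function(geom, target, name = "distance") {
  stopifnot(inherits(geom, "vraster"))
  xs <- raster_xcoords(geom); ys <- raster_ycoords(geom)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  if (is.matrix(target) && is.logical(target)) {
    if (!any(target)) stop("distance_covariate: empty mask")
    if (!all(dim(target) == dim(geom$values))) stop("mask dimensions differ from grid")
    cells <- which(target)
    ij <- arrayInd(cells, dim(target))
    D <- matrix(Inf, nrow(geom$values), ncol(geom$values))
    for (k in seq_len(nrow(ij))) {
      d <- sqrt((X - xs[ij[k, 2L]])^2 + (Y - ys[ij[k, 1L]])^2)
      D <- pmin(D, d)
    }
  } else {
    target <- as.numeric(target)
    if (length(target) != 2L || !all(is.finite(target)))
      stop("target must be a finite (x, y) point or a logical mask")
    D <- sqrt((X - target[1L])^2 + (Y - target[2L])^2)
  }
  out <- vraster(D, geom$x0, geom$y0, geom$h, name = name)
  ## the gradient direction is undefined where the distance is 0; mark those
  ## cells so gradient_field() can zero them (the symmetric choice)
  out$zero_cells <- which(D == 0)
  out
}

#' Gradient field of a raster by finite differences
#'
#' Central differences in the interior, one-sided differences on the edges.
#' Units: covariate units per km. The field is what enters the velocity
#' regression as a potential driver of movement.
#'
#' @param r a filled [vraster()] with at least 2 rows and columns.
#' @return object of class `gradient_field`: `vraster`s `gx`, `gy` on the
#'   parent grid, plus the parent name.
#' @export
gradient_field <- function(r) {
  stopifnot(inherits(r, "vraster"))
  v <- r$values
  if (any(is.na(v))) stop("gradient_field: raster '", r$name, "' has unfilled missing cells")
  R <- nrow(v); C <- ncol(v)
  if (R < 2L || C < 2L) stop("need at least a 2 x 2 grid")
  h <- r$h
  gx <- v; gy <- v
  ## d/dx runs along columns
  if (C > 2L) gx[, 2:(C - 1L)] <- (v[, 3:C] - v[, 1:(C - 2L)]) / (2 * h)
  gx[, 1L] <- (v[, 2L] - v[, 1L]) / h
  gx[, C] <- (v[, C] - v[, C - 1L]) / h
  ## d/dy runs along rows
  if (R > 2L) gy[2:(R - 1L), ] <- (v[3:R, ] - v[1:(R - 2L), ]) / (2 * h)
  gy[1L, ] <- (v[2L, ] - v[1L, ]) / h
  gy[R, ] <- (v[R, ] - v[R - 1L, ]) / h
  if (!is.null(r$zero_cells) && length(r$zero_cells)) {
    gx[r$zero_cells] <- 0
    gy[r$zero_cells] <- 0
  }
  structure(list(gx = vraster(gx, r$x0, r$y0, h, paste0(r$name, "_dx")),
                 gy = vraster(gy, r$x0, r$y0, h, paste0(r$name, "_dy")),
                 parent = r$name),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat("Gradient field of '", x$parent, "' (", nrow(x$gx$values), " x ",
      ncol(x$gx$values), " cells)\n", sep = "")
  invisible(x)
}

## bilinear interpolation of one raster at n points; returns NA outside the
## extent of cell centres
bilinear_many <- function(r, px, py) {
  xs <- raster_xcoords(r); ys <- raster_ycoords(r)
  C <- length(xs); R <- length(ys)
  u <- (px - r$x0) / r$h + 1   # fractional column index
  v <- (py - r$y0) / r$h + 1   # fractional row index
  out <- rep(NA_real_, length(px))
  ok <- u >= 1 & u <= C & v >= 1 & v <= R & is.finite(u) & is.finite(v)
  if (!any(ok)) return(out)
  u <- u[ok]; v <- v[ok]
  j0 <- pmin(pmax(floor(u), 1L), C - 1L)
  i0 <- pmin(pmax(floor(v), 1L), R - 1L)
  fu <- u - j0; fv <- v - i0
  m <- r$values
  idx <- function(i, j) m[cbind(i, j)]
  val <- (1 - fu) * (1 - fv) * idx(i0, j0) +
    fu * (1 - fv) * idx(i0, j0 + 1L) +
    (1 - fu) * fv * idx(i0 + 1L, j0) +
    fu * fv * idx(i0 + 1L, j0 + 1L)
  out[ok] <- val
  out
}

#' Evaluate a gradient field at point locations
#'
#' Bilinear interpolation of each gradient component at arbitrary planar
#' locations within the grid extent.
#'
#' @param field a [gradient_field()].
#' @param xy numeric length-2 point or an n x 2 matrix of points (km).
#' @param na_outside if `TRUE`, points outside the extent yield `NA` rows
#'   (the fitting layer drops those steps); if `FALSE` (default) they raise
#'   an error.
#' @return n x 2 matrix of gradient vectors (columns d/dx, d/dy).
#' @export
eval_gradient <- function(field, xy, na_outside = FALSE) {
  stopifnot(inherits(field, "gradient_field"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  gx <- bilinear_many(field$gx, xy[, 1L], xy[, 2L])
  gy <- bilinear_many(field$gy, xy[, 1L], xy[, 2L])
  if (!na_outside && (anyNA(gx) || anyNA(gy))) {
    bad <- which(is.na(gx) | is.na(gy))[1L]
    stop("location (", xy[bad, 1L], ", ", xy[bad, 2L],
         ") outside the extent of gradient field '", field$parent, "'")
  }
  cbind(gx = gx, gy = gy)
}
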