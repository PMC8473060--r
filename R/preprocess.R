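#' Trajectory-hull outlier gate
#'
#' Removes far-range returns: a survey polygon is the convex hull of the
#' trajectory's XY positions, and only points inside it, or within `buffer`
#' meters of its boundary, are kept. Heights are ignored by the test.
#'
#' @param cloud a [point_cloud()].
#' @param traj a [trajectory()] with at least 3 non-collinear XY positions.
#' @param buffer meters, `>= 0`.
#' @return the retained [point_cloud()]; the logical keep mask is attached
#'   as attribute `"kept"`.
#' @export
hull_outlier_filter <- function(cloud, traj, buffer = 1) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(traj, "trajectory"))
  if (buffer < 0) stop("hull_outlier_filter: buffer must be >= 0")
  hull <- trajectory_hull(traj)
  keep <- points_in_hull(cloud$coords[, 1:2, drop = FALSE], hull, buffer)
  out <- cloud_subset(cloud, keep)
  attr(out, "kept") <- keep
  out
}

# convex hull vertices (counter-clockwise) of the trajectory XY positions
trajectory_hull <- function(traj) {
  xy <- unique(traj$positions[, 1:2, drop = FALSE])
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  if (nrow(v) < 3L || abs(polygon_area(v)) < 1e-12)
    stop("hull_outlier_filter: trajectory XY positions are collinear; ",
         "no survey polygon can be derived")
  if (polygon_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:length(x), 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# points (n x 2) inside a CCW convex polygon or within buffer of its boundary
points_in_hull <- function(xy, hull, buffer) {
  n <- nrow(xy)
  if (n == 0L) return(logical(0))
  nv <- nrow(hull)
  inside <- rep(TRUE, n)
  dmin2 <- rep(Inf, n)
  for (e in seq_len(nv)) {
    a <- hull[e, ]; b <- hull[if (e == nv) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    rx <- xy[, 1] - a[1]; ry <- xy[, 2] - a[2]
    inside <- inside & (ex * ry - ey * rx >= 0)        # left of CCW edge
    len2 <- ex^2 + ey^2
    t <- pmin(1, pmax(0, (rx * ex + ry * ey) / len2))  # clamp to segment
    dmin2 <- pmin(dmin2, (rx - t * ex)^2 + (ry - t * ey)^2)
  }
  inside | dmin2 <= buffer^2
}

#' Morphological ground filter
#'
#' Separates ground from vegetation on a gridded height profile: the cloud
#' is rasterized to a minimum-z grid (cell size `morph_window / 5`), a
#' grayscale opening (erosion then dilation) with a square structuring
#' element of width `morph_window` is applied, and a point is classified
#' ground iff its height above the opened surface at its cell is at most
#' `morph_height_tol`. Ground and non-ground partition the input exactly.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param params a [preprocess_params()].
#' @return a list with `ground` and `nonground` point clouds and the logical
#'   vector `is_ground`.
#' @export
morphological_ground_filter <- function(cloud, params = preprocess_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (npoints(cloud) == 0L)
    stop("morphological_ground_filter: empty cloud")
  cell <- params$morph_window / 5
  xy <- cloud$coords[, 1:2, drop = FALSE]
  z <- cloud$coords[, 3]
  x0 <- min(xy[, 1]); y0 <- min(xy[, 2])
  nx <- max(1L, ceiling((max(xy[, 1]) - x0) / cell + 1e-9))
  ny <- max(1L, ceiling((max(xy[, 2]) - y0) / cell + 1e-9))
  ix <- pmin(nx, pmax(1L, floor((xy[, 1] - x0) / cell) + 1L))
  iy <- pmin(ny, pmax(1L, floor((xy[, 2] - y0) / cell) + 1L))
  idx <- (iy - 1L) * nx + ix

  minz <- matrix(NA_real_, nx, ny)
  ord <- order(idx, z)
  first <- !duplicated(idx[ord])
  minz[idx[ord][first]] <- z[ord][first]

  opened <- morph_open(minz, r = 2L) # 5x5 SE = morph_window wide
  is_ground <- (z - opened[idx]) <= params$morph_height_tol
  if (!any(is_ground))
    message("morphological_ground_filter: no ground points found")
  list(ground = cloud_subset(cloud, is_ground),
       nonground = cloud_subset(cloud, !is_ground),
       is_ground = is_ground)
}

# grayscale opening of a raster with (2r+1)^2 square SE; NA cells are
# treated as empty (ignored by min/max) and may be filled by the operation
morph_open <- function(m, r) {
  dilate_of <- function(mm, f, fill) {
    out <- matrix(fill, nrow(mm), ncol(mm))
    mm[is.na(mm)] <- fill
    for (dx in -r:r) for (dy in -r:r)
      out <- f(out, shift_mat(mm, dx, dy, fill))
    out
  }
  er <- dilate_of(m, pmin, Inf)
  op <- dilate_of(er, pmax, -Inf)
  op[!is.finite(op)] <- NA_real_
  op
}

shift_mat <- function(m, dx, dy, fill) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  xs <- seq_len(nx) - dx; ys <- seq_len(ny) - dy
  okx <- xs >= 1L & xs <= nx; oky <- ys >= 1L & ys <= ny
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

#' Build a DTM by inverse-distance weighting
#'
#' Interpolates ground elevations on a regular grid: each cell center gets
#' the IDW mean of its `idw_neighbors` nearest ground points with weights
#' `1/d^idw_power`; a ground point closer than 1e-9 m to the center is used
#' directly. Every cell is filled.
#'
#' @param ground a non-empty ground [point_cloud()].
#' @param params a [preprocess_params()].
#' @param extent optional `c(xmin, xmax, ymin, ymax)` the grid must cover
#'   (e.g. the filtered cloud's bounding box); defaults to the ground
#'   cloud's own bounding box.
#' @return an object of class `dtm_grid`: `origin` (lower-left corner),
#'   `cell_size`, and elevation matrix `z` indexed `[ix, iy]`.
#' @export
build_dtm <- function(ground, params = preprocess_params(), extent = NULL) {
  stopifnot(inherits(ground, "point_cloud"))
  if (npoints(ground) == 0L)
    stop("build_dtm: cannot build a DTM from an empty ground cloud")
  cell <- params$dtm_cell
  if (is.null(extent))
    extent <- c(range(ground$coords[, 1]), range(ground$coords[, 2]))
  x0 <- extent[1]; y0 <- extent[3]
  nx <- max(1L, ceiling((extent[2] - x0) / cell))
  ny <- max(1L, ceiling((extent[4] - y0) / cell))
  cx <- x0 + (seq_len(nx) - 0.5) * cell
  cy <- y0 + (seq_len(ny) - 0.5) * cell
  centers <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  zed <- idw_interp_cpp(ground$coords[, 1:2, drop = FALSE],
                        ground$coords[, 3], centers,
                        params$idw_neighbors, params$idw_power)
  structure(list(origin = c(x0, y0), cell_size = cell,
                 z = matrix(zed, nx, ny)),
            class = "dtm_grid")
}

#' @export
print.dtm_grid <- function(x, ...) {
  cat(sprintf("dtm_grid: %d x %d cells of %.2f m, origin (%.2f, %.2f)\n",
              nrow(x$z), ncol(x$z), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  elevation range: [%.2f, %.2f] m\n",
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE)))
  invisible(x)
}

# bilinear interpolation of the DTM at xy (n x 2); cell centers are the
# interpolation nodes; queries beyond the node lattice clamp to the edge
# (nearest-cell extrapolation)
dtm_interpolate <- function(dtm, xy) {
  nx <- nrow(dtm$z); ny <- ncol(dtm$z)
  gx <- (xy[, 1] - dtm$origin[1]) / dtm$cell_size - 0.5
  gy <- (xy[, 2] - dtm$origin[2]) / dtm$cell_size - 0.5
  i0 <- pmin(max(nx - 1L, 1L), pmax(1L, floor(gx) + 1L))
  j0 <- pmin(max(ny - 1L, 1L), pmax(1L, floor(gy) + 1L))
  fx <- if (nx > 1L) pmin(1, pmax(0, gx - (i0 - 1L))) else 0
  fy <- if (ny > 1L) pmin(1, pmax(0, gy - (j0 - 1L))) else 0
  i1 <- pmin(nx, i0 + 1L); j1 <- pmin(ny, j0 + 1L)
  z00 <- dtm$z[cbind(i0, j0)]; z10 <- dtm$z[cbind(i1, j0)]
  z01 <- dtm$z[cbind(i0, j1)]; z11 <- dtm$z[cbind(i1, j1)]
  (1 - fx) * (1 - fy) * z00 + fx * (1 - fy) * z10 +
    (1 - fx) * fy * z01 + fx * fy * z11
}

#' Normalize point heights against a DTM
#'
#' Replaces each point's z by its height above the bilinearly interpolated
#' DTM, so the ground sits at ~0 everywhere. XY coordinates and point order
#' are unchanged. Points outside the DTM extent are normalized against the
#' nearest cell and reported via a message.
#'
#' @param cloud a [point_cloud()].
#' @param dtm a `dtm_grid` from [build_dtm()].
#' @return the normalized [point_cloud()].
#' @export
normalize_heights <- function(cloud, dtm) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(dtm, "dtm_grid"))
  xy <- cloud$coords[, 1:2, drop = FALSE]
  xmax <- dtm$origin[1] + nrow(dtm$z) * dtm$cell_size
  ymax <- dtm$origin[2] + ncol(dtm$z) * dtm$cell_size
  outside <- xy[, 1] < dtm$origin[1] | xy[, 1] > xmax |
             xy[, 2] < dtm$origin[2] | xy[, 2] > ymax
  if (any(outside))
    message(sprintf(paste0("normalize_heights: %d point(s) outside the DTM",
                           " extent; nearest-cell extrapolation used"),
                    sum(outside)))
  gz <- dtm_interpolate(dtm, xy)
  coords <- cloud$coords
  coords[, 3] <- coords[, 3] - gz
  point_cloud(coords, labels = cloud$labels, source_id = cloud$source_id)
}
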