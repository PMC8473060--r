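#' Point cloud container
#'
#' A minimal in-memory container for a 3D point cloud: an `n x 3` coordinate
#' matrix in meters, optional per-point integer labels (`0` = noise,
#' `>= 1` = tree id), and a free-text provenance tag.
#'
#' @param coords numeric matrix (or data frame) with columns x, y, z in meters.
#' @param labels optional integer vector, one per point; `0` means noise,
#'   positive values are tree ids.
#' @param source_id free-text provenance tag.
#' @return an object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(cbind(runif(5), runif(5), runif(5)))
#' npoints(pc)
#' @export
point_cloud <- function(coords, labels = NULL, source_id = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) < 3L)
    stop("point_cloud: 'coords' must have three columns (x, y, z)")
  coords <- coords[, 1:3, drop = FALSE]
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (nrow(coords) > 0L && !all(is.finite(coords)))
    stop("point_cloud: all coordinates must be finite")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(coords))
      stop("point_cloud: length(labels) must equal the number of points")
  }
  structure(list(coords = coords, labels = labels,
                 source_id = as.character(source_id)[1]),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param x a `point_cloud`.
#' @return integer count.
#' @export
npoints <- function(x) nrow(x$coords)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", npoints(x),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  if (npoints(x) > 0) {
    r <- apply(x$coords, 2, range)
    cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  if (!is.null(x$labels)) {
    nt <- length(unique(x$labels[x$labels > 0L]))
    cat(sprintf("  labels: %d tree id(s), %d noise point(s)\n",
                nt, sum(x$labels == 0L)))
  }
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  df <- as.data.frame(x$coords)
  if (!is.null(x$labels)) df$tree_id <- x$labels
  df
}

# internal: subset preserving labels
cloud_subset <- function(cloud, idx) {
  point_cloud(cloud$coords[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx],
              source_id = cloud$source_id)
}

#' Scanner trajectory
#'
#' Ordered scanner positions (an x, y, z polyline in meters) with optional
#' monotone timestamps. The convex hull of the XY positions defines the
#' survey polygon used by [hull_outlier_filter()].
#'
#' @param positions numeric matrix (or data frame) with columns x, y, z.
#' @param timestamps optional numeric vector, non-decreasing.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(positions, timestamps = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) < 3L)
    stop("trajectory: 'positions' must have three columns (x, y, z)")
  positions <- positions[, 1:3, drop = FALSE]
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  if (nrow(positions) < 3L)
    stop("trajectory: at least 3 positions are required")
  if (!is.null(timestamps)) {
    timestamps <- as.numeric(timestamps)
    if (length(timestamps) != nrow(positions))
      stop("trajectory: one timestamp per position required")
    if (is.unsorted(timestamps))
      stop("trajectory: timestamps must be non-decreasing")
  }
  structure(list(positions = positions, timestamps = timestamps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d positions, length %.1f m\n",
              nrow(x$positions),
              sum(sqrt(rowSums(diff(x$positions)^2)))))
  invisible(x)
}
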