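#' Deterministic DBSCAN clustering
#'
#' Density-based clustering with the standard core/border/noise semantics:
#' a point is a core point iff it has at least `min_points` neighbors within
#' `eps` (inclusive, counting itself); clusters are the connected components
#' of core points under eps-reachability; a non-core point with a core
#' neighbor is a border point and joins the cluster of its lowest-indexed
#' core neighbor; all remaining points are noise.
#'
#' Clusters are numbered 1, 2, ... by ascending lowest core-point index, so
#' the labeling never depends on traversal order and is reproducible across
#' platforms.
#'
#' @param points numeric matrix of coordinates (n x 2 for the trunk layer,
#'   n x 3 for per-cylinder subclustering).
#' @param eps neighborhood radius in meters, `> 0`.
#' @param min_points minimum neighbor count for a core point (self
#'   included), `>= 1`.
#' @return integer vector of length n: `0` for noise, `1..k` cluster ids.
#' @examples
#' pts <- rbind(c(0, 0), c(0.5, 0), c(10, 10))
#' dbscan(pts, eps = 1, min_points = 2)
#' @export
dbscan <- function(points, eps, min_points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!is.finite(eps) || eps <= 0) stop("dbscan: eps must be > 0")
  min_points <- as.integer(min_points)
  if (min_points < 1L) stop("dbscan: min_points must be >= 1")
  dbscan_labels_cpp(points, eps, min_points)
}
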