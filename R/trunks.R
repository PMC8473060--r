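#' Extract the trunk layer
#'
#' Returns the points of a height-normalized cloud whose z lies in the
#' trunk-layer slab `[slab_zmin, slab_zmax]` (both bounds inclusive). Stems
#' cross this slab as dense, compact XY clusters; the default bounds
#' (1.0-1.5 m) sit above typical shrubs and below most crowns, near breast
#' height.
#'
#' @param cloud a height-normalized [point_cloud()].
#' @param params a [seg_params()].
#' @return the slab [point_cloud()]; original point indices are attached as
#'   attribute `"indices"`.
#' @export
extract_trunk_layer <- function(cloud, params = seg_params()) {
  stopifnot(inherits(cloud, "point_cloud"))
  z <- cloud$coords[, 3]
  idx <- which(z >= params$slab_zmin & z <= params$slab_zmax)
  if (length(idx) == 0L)
    stop("extract_trunk_layer: no points in the trunk slab [",
         params$slab_zmin, ", ", params$slab_zmax, "] m; is the cloud ",
         "height-normalized?")
  out <- cloud_subset(cloud, idx)
  attr(out, "indices") <- idx
  out
}

#' Detect trunks in the trunk layer
#'
#' Projects the trunk slab to XY, clusters it with [dbscan()] at
#' `eps_trunk`/`min_points`, and turns every cluster into a trunk candidate
#' whose centroid — the tree location estimate — is the equal-weight center
#' of mass of the member XY coordinates, i.e. their arithmetic mean.
#' DBSCAN noise points are dropped from trunk candidacy.
#'
#' @param cloud a height-normalized [point_cloud()].
#' @param params a [seg_params()].
#' @return a list of `trunk_cluster` objects, each with `trunk_id`,
#'   `member_indices` (into `cloud`) and `centroid_xy`.
#' @export
detect_trunks <- function(cloud, params = seg_params()) {
  slab <- extract_trunk_layer(cloud, params)
  idx <- attr(slab, "indices")
  cl <- dbscan(slab$coords[, 1:2, drop = FALSE],
               eps = params$eps_trunk, min_points = params$min_points)
  k <- max(cl)
  if (k == 0L)
    stop("detect_trunks: no trunk clusters found; consider increasing ",
         "eps_trunk (", params$eps_trunk, " m) or lowering min_points (",
         params$min_points, ")")
  lapply(seq_len(k), function(i) {
    members <- which(cl == i)
    structure(list(trunk_id = i,
                   member_indices = idx[members],
                   centroid_xy = colMeans(
                     slab$coords[members, 1:2, drop = FALSE])),
              class = "trunk_cluster")
  })
}

#' @export
print.trunk_cluster <- function(x, ...) {
  cat(sprintf("trunk_cluster %d: %d points, centroid (%.2f, %.2f)\n",
              x$trunk_id, length(x$member_indices),
              x$centroid_xy[1], x$centroid_xy[2]))
  invisible(x)
}
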