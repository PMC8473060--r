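#' Candidate cylinder radii
#'
#' For each detected trunk, the distance from its centroid to the nearest
#' other trunk centroid is the *candidate radius* of that tree's infinite
#' vertical cylinder.
#'
#' @param trunks list of `trunk_cluster` objects from [detect_trunks()].
#' @param single_trunk_radius radius used when only one trunk exists and
#'   the nearest-neighbor distance is undefined; defaults to `NA`, in which
#'   case [run_voxelization()] substitutes the cloud's XY bounding-circle
#'   radius.
#' @return named numeric vector, one radius (meters) per trunk id.
#' @export
candidate_radii <- function(trunks, single_trunk_radius = NA_real_) {
  n <- length(trunks)
  if (n == 0L) stop("candidate_radii: no trunks")
  centers <- t(vapply(trunks, `[[`, numeric(2), "centroid_xy"))
  ids <- vapply(trunks, `[[`, integer(1), "trunk_id")
  if (n == 1L) return(setNames(single_trunk_radius, ids))
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  r <- apply(d, 1, min)
  if (any(r == 0)) {
    pair <- which(d == 0, arr.ind = TRUE)[1, ]
    stop("candidate_radii: trunks ", ids[pair[1]], " and ", ids[pair[2]],
         " have identical centroids (degenerate zero radius)")
  }
  setNames(r, ids)
}

#' Extract the points of an infinite vertical cylinder
#'
#' @param cloud a [point_cloud()].
#' @param center_xy cylinder axis location `c(x, y)` in meters.
#' @param radius cylinder radius in meters, `> 0`; membership is the closed
#'   disk (boundary included) and z is unconstrained.
#' @param available integer indices still up for grabs (defaults to all).
#' @return integer indices of `available` points inside the cylinder.
#' @export
extract_cylinder <- function(cloud, center_xy, radius,
                             available = seq_len(npoints(cloud))) {
  if (!is.finite(radius) || radius <= 0)
    stop("extract_cylinder: radius must be > 0")
  dx <- cloud$coords[available, 1] - center_xy[1]
  dy <- cloud$coords[available, 2] - center_xy[2]
  available[dx * dx + dy * dy <= radius * radius]
}

#' Subcluster a cylinder's points
#'
#' Runs 3D [dbscan()] at `eps_cylinder`/`min_points_cyl` on the cylinder
#' members. Low radii are intended: surrounding crown material splits into
#' small subclusters (deliberate oversegmentation) instead of gluing to the
#' stem, and the merge stage reassembles trees.
#'
#' @param cloud a [point_cloud()].
#' @param members integer indices of the cylinder's points.
#' @param params a [seg_params()].
#' @return list with `subclusters` (list of index vectors, indices into the
#'   cloud) and `noise` (indices rejected by DBSCAN).
#' @export
subcluster_cylinder <- function(cloud, members, params = seg_params()) {
  if (length(members) == 0L)
    return(list(subclusters = list(), noise = integer(0)))
  cl <- dbscan(cloud$coords[members, , drop = FALSE],
               eps = params$eps_cylinder,
               min_points = params$min_points_cyl)
  k <- max(cl)
  list(subclusters = lapply(seq_len(max(k, 0L)),
                            function(i) members[cl == i]),
       noise = members[cl == 0L])
}

#' Iterative cylinder voxelization
#'
#' Partitions the cloud into per-tree cylinder point sets: trunks are
#' visited in ascending candidate-radius order (ties broken by trunk id, so
#' small cylinders claim points before a large neighbor can swallow them);
#' each iteration extracts the still-available points inside that trunk's
#' infinite cylinder, subclusters them in 3D, and removes them from the
#' available pool. Points captured by no cylinder, plus per-cylinder DBSCAN
#' noise, form the discarded set `C* = C - U C_i`.
#'
#' @param cloud a height-normalized [point_cloud()] (vegetation points).
#' @param trunks list of `trunk_cluster` objects.
#' @param params a [seg_params()].
#' @return list with `cylinders` (list of `cylinder_cell`: `trunk_id`,
#'   `center_xy`, `radius`, `member_indices`, `subclusters`, `noise`) and
#'   `discarded` (integer indices).
#' @export
run_voxelization <- function(cloud, trunks, params = seg_params()) {
  if (length(trunks) == 0L) stop("run_voxelization: no trunks")
  radii <- candidate_radii(trunks)
  if (length(trunks) == 1L && is.na(radii[1])) {
    # single-trunk plot: the whole plot is one tree; use the XY
    # bounding-circle radius around the trunk
    ctr <- trunks[[1]]$centroid_xy
    radii[1] <- sqrt(max((cloud$coords[, 1] - ctr[1])^2 +
                         (cloud$coords[, 2] - ctr[2])^2))
  }
  ord <- order(radii, vapply(trunks, `[[`, integer(1), "trunk_id"))
  available <- rep(TRUE, npoints(cloud))
  cylinders <- vector("list", length(trunks))
  all_noise <- integer(0)
  for (i in ord) {
    tr <- trunks[[i]]
    members <- extract_cylinder(cloud, tr$centroid_xy, radii[i],
                                available = which(available))
    available[members] <- FALSE
    sub <- subcluster_cylinder(cloud, members, params)
    all_noise <- c(all_noise, sub$noise)
    cylinders[[i]] <- structure(
      list(trunk_id = tr$trunk_id, center_xy = tr$centroid_xy,
           radius = unname(radii[i]),
           member_indices = members,
           subclusters = sub$subclusters, noise = sub$noise),
      class = "cylinder_cell")
  }
  list(cylinders = cylinders,
       discarded = sort(c(which(available), all_noise)))
}
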