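#' Vertical continuity of a subcluster
#'
#' Classifies a subcluster as ground-connected or floating by its point
#' density over height: a z-histogram with bin width `continuity_bin`
#' (bins anchored at height 0) is built, and the subcluster is
#' ground-connected iff (a) its lowest occupied bin starts at or below
#' `continuity_ground_max` and (b) no run of `continuity_gap_bins` or more
#' consecutive empty bins occurs inside its own vertical extent.
#'
#' @param cloud a height-normalized [point_cloud()].
#' @param subcluster integer indices of the subcluster's points.
#' @param params a [seg_params()].
#' @return `TRUE` if ground-connected, `FALSE` if floating.
#' @export
classify_continuity <- function(cloud, subcluster, params = seg_params()) {
  if (length(subcluster) == 0L)
    stop("classify_continuity: empty subcluster")
  z <- cloud$coords[subcluster, 3]
  bins <- sort(unique(floor(z / params$continuity_bin)))
  starts_at_ground <- bins[1] * params$continuity_bin <=
    params$continuity_ground_max
  gaps <- if (length(bins) > 1L) diff(bins) - 1L else integer(0)
  no_discontinuity <- !any(gaps >= params$continuity_gap_bins)
  starts_at_ground && no_discontinuity
}

# internal constructor for the merge stage
make_segment <- function(tree_id, point_indices, ground_connected, stem_xy) {
  structure(list(tree_id = as.integer(tree_id),
                 point_indices = as.integer(point_indices),
                 ground_connected = isTRUE(ground_connected),
                 stem_xy = as.numeric(stem_xy)),
            class = "segment")
}

#' Merge floating segments into ground-connected trees
#'
#' Every floating segment is assigned to the ground-connected segment that
#' minimizes the cluster-to-cluster distance, taken as the minimum 3D
#' point-to-point Euclidean distance (it respects touching branch
#' geometry); exact ties break toward the lower tree id. Ground-connected
#' segments of the same tree are unioned, so the output has exactly one
#' segment per tree.
#'
#' @param segments list of `segment` objects (see [segment_trees()]
#'   internals); at least one must be ground-connected.
#' @param cloud the [point_cloud()] the indices refer to.
#' @return list of merged `segment` objects, one per tree id, sorted by
#'   tree id.
#' @export
merge_floating <- function(segments, cloud) {
  gc_idx <- which(vapply(segments, `[[`, logical(1), "ground_connected"))
  if (length(gc_idx) == 0L)
    stop("merge_floating: no ground-connected segment exists; ",
         "cannot anchor any tree")
  # deterministic target order: ascending tree id, then position
  gc_idx <- gc_idx[order(vapply(segments[gc_idx], `[[`, integer(1),
                                "tree_id"), gc_idx)]
  targets <- segments[gc_idx]
  tgt_coords <- lapply(targets, function(s)
    cloud$coords[s$point_indices, , drop = FALSE])
  assigned_to <- integer(0) # per floating segment: index into targets
  fl_idx <- setdiff(seq_along(segments), gc_idx)
  for (f in fl_idx) {
    a <- cloud$coords[segments[[f]]$point_indices, , drop = FALSE]
    d <- vapply(tgt_coords, function(b) min(nn_dist_cpp(a, b)), numeric(1))
    assigned_to[length(assigned_to) + 1L] <- which.min(d)
  }
  # union per tree id
  ids <- sort(unique(vapply(targets, `[[`, integer(1), "tree_id")))
  out <- lapply(ids, function(id) {
    own <- which(vapply(targets, `[[`, integer(1), "tree_id") == id)
    pts <- unlist(lapply(targets[own], `[[`, "point_indices"))
    fl_here <- fl_idx[assigned_to %in% own]
    pts <- c(pts, unlist(lapply(segments[fl_here], `[[`, "point_indices")))
    make_segment(id, sort(unique(pts)), TRUE, targets[[own[1]]]$stem_xy)
  })
  out
}

#' Assign discarded points or declare them noise
#'
#' Each discarded point joins the segment whose nearest member point is
#' closest, provided that distance is strictly below the noise threshold
#' `d*`; otherwise the point goes to the noise set (label 0). A point at
#' exactly `d*` is noise. Nearest-member distance (not centroid distance)
#' is used so tall-crown points are not misassigned.
#'
#' @param discarded integer indices of the discarded points.
#' @param segments list of merged `segment` objects ([merge_floating()]).
#' @param cloud the [point_cloud()] the indices refer to.
#' @param d_star noise threshold in meters.
#' @return list with `segment_of` (per discarded point, the position in
#'   `segments` it joins, or 0 for noise) and `noise` (indices).
#' @export
assign_discarded <- function(discarded, segments, cloud, d_star) {
  nd <- length(discarded)
  if (nd == 0L)
    return(list(segment_of = integer(0), noise = integer(0)))
  a <- cloud$coords[discarded, , drop = FALSE]
  best_d <- rep(Inf, nd)
  best_s <- integer(nd)
  ord <- order(vapply(segments, `[[`, integer(1), "tree_id"))
  for (s in ord) {
    d <- nn_dist_cpp(a, cloud$coords[segments[[s]]$point_indices, ,
                                     drop = FALSE])
    better <- d < best_d # strict: ties keep the lower tree id
    best_d[better] <- d[better]
    best_s[better] <- s
  }
  joins <- best_d < d_star
  list(segment_of = ifelse(joins, best_s, 0L),
       noise = discarded[!joins])
}

#' Finalize a segmentation into per-point labels
#'
#' Assigns contiguous tree ids 1..N in ascending stem x (then y) order and
#' builds the per-point label vector (0 = noise / unassigned).
#'
#' @param n_points number of points in the cloud being labeled.
#' @param segments list of merged `segment` objects.
#' @param noise integer indices labeled 0.
#' @param stage_counts named list of per-stage diagnostics to carry along.
#' @return list with `labels` (integer, length `n_points`),
#'   `tree_locations` (matrix tree_id/x/y) and `stage_counts`.
#' @export
finalize_segmentation <- function(n_points, segments, noise,
                                  stage_counts = list()) {
  stems <- t(vapply(segments, `[[`, numeric(2), "stem_xy"))
  ord <- order(stems[, 1], stems[, 2])
  labels <- integer(n_points)
  locs <- matrix(NA_real_, nrow = length(segments), ncol = 3,
                 dimnames = list(NULL, c("tree_id", "x", "y")))
  for (new_id in seq_along(ord)) {
    s <- segments[[ord[new_id]]]
    labels[s$point_indices] <- new_id
    locs[new_id, ] <- c(new_id, s$stem_xy)
  }
  labels[noise] <- 0L
  stage_counts$n_trees <- length(segments)
  stage_counts$n_noise <- length(noise)
  list(labels = labels, tree_locations = locs, stage_counts = stage_counts)
}
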