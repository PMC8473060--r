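#' Segment individual trees from a ground-based LiDAR cloud
#'
#' Runs the full individual-tree segmentation pipeline: (i) far-range
#' outlier gating by the trajectory's convex hull, (ii) morphological
#' ground filtering, DTM construction by inverse-distance weighting and
#' height normalization, (iii) trunk detection by DBSCAN on a
#' breast-height slab, (iv) iterative per-tree infinite-cylinder
#' voxelization with 3D subclustering, and (v) vertical-continuity
#' classification, floating-segment merging and noise filtering with the
#' threshold `d*`. Ground points are excluded from the vegetation cloud
#' that gets segmented.
#'
#' @param cloud a [point_cloud()] in raw (unnormalized) coordinates.
#' @param traj optional [trajectory()]; when absent the hull gate is
#'   skipped with a warning.
#' @param params a [seg_params()].
#' @param pre a [preprocess_params()].
#' @param keep_cloud keep the normalized vegetation cloud inside the fit
#'   (needed by [predict.stemseg()] and [match_trees()]).
#' @return an object of class `stemseg` with per-point `labels` on the
#'   input cloud (`0` = noise / ground / removed), `tree_locations`
#'   (`coef()`), per-stage `stage_counts`, the `dtm`, the detected
#'   `trunks`, and the parameter sets used.
#' @seealso [simulate_forest()] for synthetic scenes, [match_trees()] and
#'   [segmentation_metrics()] for validation.
#' @examples
#' scene <- simulate_forest(forest_spec(n_trees = 4, plot_size = c(18, 18),
#'                                      seed = 7))
#' fit <- segment_trees(scene$cloud, scene$trajectory)
#' coef(fit)
#' @export
segment_trees <- function(cloud, traj = NULL, params = seg_params(),
                          pre = preprocess_params(), keep_cloud = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  cl <- match.call()
  n0 <- npoints(cloud)
  counts <- list(n_input = n0)

  if (is.null(traj)) {
    warning("segment_trees: no trajectory given; hull outlier filter ",
            "skipped")
    filtered <- cloud
    kept <- rep(TRUE, n0)
    hull <- NULL
  } else {
    filtered <- hull_outlier_filter(cloud, traj, pre$hull_buffer)
    kept <- attr(filtered, "kept")
    hull <- trajectory_hull(traj)
  }
  counts$n_after_hull <- npoints(filtered)

  gf <- morphological_ground_filter(filtered, pre)
  counts$n_ground <- npoints(gf$ground)
  dtm <- build_dtm(gf$ground, pre,
                   extent = c(range(filtered$coords[, 1]),
                              range(filtered$coords[, 2])))
  norm <- normalize_heights(filtered, dtm)
  veg <- cloud_subset(norm, !gf$is_ground)
  counts$n_vegetation <- npoints(veg)

  trunks <- detect_trunks(veg, params)
  counts$n_trunks <- length(trunks)

  vox <- run_voxelization(veg, trunks, params)
  counts$n_discarded_raw <- length(vox$discarded)

  segments <- list()
  for (cy in vox$cylinders) {
    for (sub in cy$subclusters) {
      gc <- classify_continuity(veg, sub, params)
      segments[[length(segments) + 1L]] <-
        make_segment(cy$trunk_id, sub, gc, cy$center_xy)
    }
  }
  counts$n_floating <- sum(!vapply(segments, `[[`, logical(1),
                                   "ground_connected"))
  merged <- merge_floating(segments, veg)

  asg <- assign_discarded(vox$discarded, merged, veg,
                          params$noise_threshold)
  for (s in seq_along(merged)) {
    add <- vox$discarded[asg$segment_of == s]
    if (length(add))
      merged[[s]]$point_indices <-
        sort(c(merged[[s]]$point_indices, add))
  }
  counts$n_assigned <- sum(asg$segment_of > 0L)

  fin <- finalize_segmentation(npoints(veg), merged, asg$noise, counts)

  labels <- integer(n0)
  veg_orig <- which(kept)[!gf$is_ground]
  labels[veg_orig] <- fin$labels

  structure(list(
    labels = labels,
    tree_locations = fin$tree_locations,
    stage_counts = fin$stage_counts,
    params = params, pre = pre,
    dtm = dtm, trunks = trunks, hull = hull,
    veg_cloud = if (keep_cloud) veg,
    veg_indices = veg_orig,
    veg_labels = fin$labels,
    call = cl), class = "stemseg")
}

#' @export
print.stemseg <- function(x, ...) {
  sc <- x$stage_counts
  cat("Individual tree segmentation (stemseg)\n")
  cat(sprintf("  input points:      %d\n", sc$n_input))
  cat(sprintf("  after hull gate:   %d\n", sc$n_after_hull))
  cat(sprintf("  ground / veg:      %d / %d\n", sc$n_ground,
              sc$n_vegetation))
  cat(sprintf("  trunks detected:   %d\n", sc$n_trunks))
  cat(sprintf("  trees:             %d\n", sc$n_trees))
  cat(sprintf("  noise points:      %d\n", sc$n_noise))
  cat(sprintf("  params: eps_trunk = %.3g m, eps_cylinder = %.3g m, ",
              x$params$eps_trunk, x$params$eps_cylinder))
  cat(sprintf("d* = %.3g m\n", x$params$noise_threshold))
  invisible(x)
}

#' @export
summary.stemseg <- function(object, ...) {
  lab <- object$labels
  sizes <- table(factor(lab[lab > 0L],
                        levels = seq_len(nrow(object$tree_locations))))
  out <- data.frame(object$tree_locations,
                    n_points = as.integer(sizes))
  structure(list(trees = out, stage_counts = object$stage_counts,
                 params = object$params),
            class = "summary.stemseg")
}

#' @export
print.summary.stemseg <- function(x, ...) {
  cat(sprintf("%d trees segmented, %d noise points\n",
              x$stage_counts$n_trees, x$stage_counts$n_noise))
  print(x$trees, row.names = FALSE)
  invisible(x)
}

#' Stem map of a fitted segmentation
#'
#' @param object a `stemseg` fit.
#' @param ... unused.
#' @return matrix with columns `tree_id`, `x`, `y` (meters).
#' @export
coef.stemseg <- function(object, ...) object$tree_locations

#' Per-point tree labels of a fitted segmentation
#'
#' @param object a `stemseg` fit.
#' @param ... unused.
#' @return integer vector over the input cloud: `0` noise/ground/removed,
#'   `>= 1` tree id.
#' @export
labels.stemseg <- function(object, ...) object$labels

#' Plot a fitted segmentation
#'
#' Draws the stem map over the (subsampled) vegetation points in XY,
#' colored by tree, with the survey hull when available.
#'
#' @param x a `stemseg` fit.
#' @param max_points at most this many vegetation points are drawn.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stemseg <- function(x, max_points = 20000, ...) {
  if (is.null(x$veg_cloud))
    stop("plot.stemseg: fit was made with keep_cloud = FALSE")
  xy <- x$veg_cloud$coords[, 1:2, drop = FALSE]
  lab <- x$veg_labels
  n <- nrow(xy)
  if (n > max_points) {
    s <- seq(1L, n, length.out = max_points)
    xy <- xy[s, , drop = FALSE]; lab <- lab[s]
  }
  cols <- ifelse(lab == 0L, "grey70",
                 grDevices::hcl.colors(max(1L, max(lab)), "Dark 3")[
                   pmax(lab, 1L)])
  graphics::plot(xy, col = cols, pch = ".", asp = 1,
                 xlab = "x [m]", ylab = "y [m]", ...)
  if (!is.null(x$hull))
    graphics::polygon(x$hull, border = "grey40", lty = 2)
  graphics::points(x$tree_locations[, "x"], x$tree_locations[, "y"],
                   pch = 4, cex = 1.2, lwd = 2)
  graphics::text(x$tree_locations[, "x"], x$tree_locations[, "y"],
                 labels = x$tree_locations[, "tree_id"], pos = 3,
                 cex = 0.7)
  invisible(x)
}

#' Assign new points to segmented trees
#'
#' Labels new (already height-normalized, same frame) points by the
#' nearest-member rule used for discarded points: a point joins the tree
#' whose nearest member point is strictly closer than `d*`, else noise.
#'
#' @param object a `stemseg` fit made with `keep_cloud = TRUE`.
#' @param newdata a [point_cloud()] or an `n x 3` coordinate matrix.
#' @param ... unused.
#' @return integer labels for the new points.
#' @export
predict.stemseg <- function(object, newdata, ...) {
  if (is.null(object$veg_cloud))
    stop("predict.stemseg: fit was made with keep_cloud = FALSE")
  coords <- if (inherits(newdata, "point_cloud")) newdata$coords
            else as.matrix(newdata)
  ids <- sort(unique(object$veg_labels[object$veg_labels > 0L]))
  best_d <- rep(Inf, nrow(coords))
  best <- integer(nrow(coords))
  for (id in ids) {
    d <- nn_dist_cpp(coords,
                     object$veg_cloud$coords[object$veg_labels == id, ,
                                             drop = FALSE])
    b <- d < best_d
    best_d[b] <- d[b]; best[b] <- id
  }
  ifelse(best_d < object$params$noise_threshold, best, 0L)
}
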