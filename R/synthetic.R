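#' Synthetic forest scene specification
#'
#' Describes a backpack-LiDAR-like forest plot: a gently sloping noisy
#' ground plane, vertical stems whose cross-section density is a Gaussian
#' ring around the trunk outline (handheld scanners place returns both
#' inside and outside the stem surface), ellipsoidal crowns atop the
#' trunks, low shrub blobs, and sparse far-range outliers beyond the
#' survey polygon. A serpentine walking trajectory between the stems is
#' generated alongside.
#'
#' @param n_trees number of trees.
#' @param plot_size `c(width, depth)` of the plot in meters.
#' @param min_spacing minimum stem-to-stem distance in meters; must exceed
#'   twice the largest trunk radius.
#' @param trunk_radius_range stem cross-section radius range, meters.
#' @param trunk_height_range crown-base height range, meters.
#' @param trunk_ring_sigma radial Gaussian spread of trunk returns about
#'   the stem outline, meters.
#' @param crown_radius_range,crown_depth_range crown ellipsoid semi-axis
#'   (horizontal) and full depth (vertical) ranges, meters.
#' @param ground_slope `c(dz/dx, dz/dy)` of the ground plane.
#' @param ground_noise_sigma vertical ground roughness, meters.
#' @param trunk_points,crown_points returns per tree on the trunk / in the
#'   crown before occlusion dropout.
#' @param ground_point_density ground returns per square meter.
#' @param n_shrubs,shrub_points low vegetation blobs (height < 0.9 m).
#' @param n_outliers far-range returns in an annulus outside the
#'   trajectory hull.
#' @param dropout_per_meter per-meter increase of the occlusion dropout
#'   probability with XY distance to the trajectory (capped at
#'   `dropout_max`); a cheap stand-in for occlusion, not a scanner model.
#' @param dropout_max cap of the dropout probability.
#' @param seed integer; the same spec and seed give a bit-identical scene.
#' @return an object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 20, plot_size = c(30, 30),
                        min_spacing = 4,
                        trunk_radius_range = c(0.10, 0.18),
                        trunk_height_range = c(4, 7),
                        trunk_ring_sigma = 0.02,
                        crown_radius_range = c(1.0, 1.8),
                        crown_depth_range = c(2, 3.5),
                        ground_slope = c(0.05, 0.03),
                        ground_noise_sigma = 0.02,
                        trunk_points = 4000, crown_points = 800,
                        ground_point_density = 20,
                        n_shrubs = 6, shrub_points = 150,
                        n_outliers = 150,
                        dropout_per_meter = 0.02, dropout_max = 0.15,
                        seed = 1) {
  spec <- list(n_trees = as.integer(n_trees), plot_size = plot_size,
               min_spacing = min_spacing,
               trunk_radius_range = trunk_radius_range,
               trunk_height_range = trunk_height_range,
               trunk_ring_sigma = trunk_ring_sigma,
               crown_radius_range = crown_radius_range,
               crown_depth_range = crown_depth_range,
               ground_slope = ground_slope,
               ground_noise_sigma = ground_noise_sigma,
               trunk_points = as.integer(trunk_points),
               crown_points = as.integer(crown_points),
               ground_point_density = ground_point_density,
               n_shrubs = as.integer(n_shrubs),
               shrub_points = as.integer(shrub_points),
               n_outliers = as.integer(n_outliers),
               dropout_per_meter = dropout_per_meter,
               dropout_max = dropout_max,
               seed = as.integer(seed))
  if (spec$n_trees < 1L) stop("forest_spec: n_trees must be >= 1")
  if (spec$min_spacing <= 2 * max(spec$trunk_radius_range))
    stop("forest_spec: min_spacing must exceed twice the largest trunk ",
         "radius")
  if (any(c(spec$plot_size, spec$trunk_radius_range,
            spec$trunk_height_range, spec$trunk_ring_sigma,
            spec$crown_radius_range, spec$crown_depth_range) <= 0))
    stop("forest_spec: sizes and ranges must be positive")
  structure(spec, class = "forest_spec")
}

#' Generate a synthetic forest scene
#'
#' Builds a labeled point cloud from a [forest_spec()]: stems are placed by
#' rejection sampling honoring `min_spacing`; trunk returns sit at radius
#' `Normal(r_tree, trunk_ring_sigma)` around the stem axis at uniform
#' heights up to the crown base; crown returns are uniform in an ellipsoid;
#' ground returns sample the sloped noisy plane; shrubs are low half-
#' ellipsoid blobs; outliers are uniform in an annulus outside the
#' trajectory hull. A distance-dependent dropout thins points far from the
#' serpentine trajectory. Everything is deterministic under the spec seed.
#'
#' @param spec a [forest_spec()].
#' @return an object of class `forest_scene`: `cloud` ([point_cloud()]),
#'   `truth` (data frame with `category` in ground/trunk/crown/shrub/
#'   outlier and `tree_id`, 0 for non-tree points), `trajectory`,
#'   `stem_map` (true per-tree x, y) and the `spec`.
#' @export
simulate_forest <- function(spec = forest_spec()) {
  stopifnot(inherits(spec, "forest_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  W <- spec$plot_size[1]; D <- spec$plot_size[2]
  margin <- max(spec$crown_radius_range) + 1.2
  gz <- function(x, y) spec$ground_slope[1] * x + spec$ground_slope[2] * y

  # stem placement by rejection sampling
  stems <- matrix(NA_real_, spec$n_trees, 2)
  placed <- 0L
  for (attempt in seq_len(500L * spec$n_trees)) {
    cand <- c(runif(1, margin, W - margin), runif(1, margin, D - margin))
    if (placed == 0L ||
        min(sqrt((stems[seq_len(placed), 1] - cand[1])^2 +
                 (stems[seq_len(placed), 2] - cand[2])^2)) >=
          spec$min_spacing) {
      placed <- placed + 1L
      stems[placed, ] <- cand
      if (placed == spec$n_trees) break
    }
  }
  if (placed < spec$n_trees)
    stop("simulate_forest: could not place ", spec$n_trees, " stems at ",
         "min_spacing ", spec$min_spacing, " m in a ", W, " x ", D,
         " m plot (infeasible spec)")

  r_tree <- runif(spec$n_trees, spec$trunk_radius_range[1],
                  spec$trunk_radius_range[2])
  h_tree <- runif(spec$n_trees, spec$trunk_height_range[1],
                  spec$trunk_height_range[2])
  cr_tree <- runif(spec$n_trees, spec$crown_radius_range[1],
                   spec$crown_radius_range[2])
  cd_tree <- runif(spec$n_trees, spec$crown_depth_range[1],
                   spec$crown_depth_range[2])

  parts <- list(); cats <- list(); tids <- list()
  add <- function(xyz, cat, tid) {
    parts[[length(parts) + 1L]] <<- xyz
    cats[[length(cats) + 1L]] <<- rep(cat, nrow(xyz))
    tids[[length(tids) + 1L]] <<- rep(tid, nrow(xyz))
  }

  for (i in seq_len(spec$n_trees)) {
    # trunk: Gaussian ring at the stem outline, uniform heights
    nt <- spec$trunk_points
    th <- runif(nt, 0, 2 * pi)
    rr <- rnorm(nt, r_tree[i], spec$trunk_ring_sigma)
    hh <- runif(nt, 0, h_tree[i])
    x <- stems[i, 1] + rr * cos(th); y <- stems[i, 2] + rr * sin(th)
    add(cbind(x, y, gz(x, y) + hh), "trunk", i)
    # crown: uniform in an ellipsoid atop the trunk
    nc <- spec$crown_points
    u <- matrix(rnorm(3 * nc), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * runif(nc)^(1 / 3)
    cx <- stems[i, 1] + cr_tree[i] * u[, 1]
    cy <- stems[i, 2] + cr_tree[i] * u[, 2]
    cz <- h_tree[i] + cd_tree[i] / 2 + (cd_tree[i] / 2) * u[, 3]
    add(cbind(cx, cy, gz(cx, cy) + cz), "crown", i)
  }

  # ground plane with roughness
  ng <- max(1L, round(spec$ground_point_density * W * D))
  gx <- runif(ng, 0, W); gy <- runif(ng, 0, D)
  add(cbind(gx, gy, gz(gx, gy) + rnorm(ng, 0, spec$ground_noise_sigma)),
      "ground", 0L)

  # shrubs: low half-ellipsoid blobs kept clear of the stems
  if (spec$n_shrubs > 0L) for (s in seq_len(spec$n_shrubs)) {
    repeat {
      ctr <- c(runif(1, 1, W - 1), runif(1, 1, D - 1))
      if (min(sqrt((stems[, 1] - ctr[1])^2 +
                   (stems[, 2] - ctr[2])^2)) > 1.5) break
    }
    sr <- runif(1, 0.4, 0.8); sh <- runif(1, 0.4, 0.8)
    n <- spec$shrub_points
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3)
    sx <- ctr[1] + sr * u[, 1]; sy <- ctr[2] + sr * u[, 2]
    add(cbind(sx, sy, gz(sx, sy) + sh * abs(u[, 3])), "shrub", 0L)
  }

  # serpentine walking path between the stems, ~1.7 m above ground
  rows <- seq(1.5, D - 1.5, by = 7.5)
  if (length(rows) < 2L || max(rows) < D - 1.5)
    rows <- unique(c(rows, D - 1.5)) # the path must reach the far edge
  wps <- do.call(rbind, lapply(seq_along(rows), function(k) {
    xs <- if (k %% 2L == 1L) c(1.5, W - 1.5) else c(W - 1.5, 1.5)
    cbind(xs, rows[k])
  }))
  pos <- do.call(rbind, lapply(seq_len(nrow(wps) - 1L), function(k) {
    a <- wps[k, ]; b <- wps[k + 1L, ]
    tt <- seq(0, 1, length.out = max(2L, ceiling(
      sqrt(sum((b - a)^2)) / 0.5)))
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }))
  pos <- pos[!duplicated(round(pos, 6)), ]
  traj <- trajectory(cbind(pos, gz(pos[, 1], pos[, 2]) + 1.7))

  # far-range outliers: annulus outside the trajectory hull
  if (spec$n_outliers > 0L) {
    ctr <- c(W, D) / 2
    rad <- sqrt(sum((c(W, D) / 2)^2))
    ro <- sqrt(runif(spec$n_outliers, (rad + 3)^2, (rad + 12)^2))
    ao <- runif(spec$n_outliers, 0, 2 * pi)
    ox <- ctr[1] + ro * cos(ao); oy <- ctr[2] + ro * sin(ao)
    add(cbind(ox, oy, gz(ox, oy) + runif(spec$n_outliers, 0, 8)),
        "outlier", 0L)
  }

  coords <- do.call(rbind, parts)
  category <- unlist(cats)
  tree_id <- unlist(tids)

  # occlusion stand-in: dropout growing with XY distance to the trajectory
  d_traj <- nn_dist_cpp(coords[, 1:2, drop = FALSE],
                        traj$positions[, 1:2, drop = FALSE])
  p_drop <- pmin(spec$dropout_max, spec$dropout_per_meter * d_traj)
  p_drop[category == "outlier"] <- 0 # outliers are kept as-is
  keep <- runif(length(p_drop)) >= p_drop

  structure(list(
    cloud = point_cloud(coords[keep, , drop = FALSE],
                        source_id = sprintf("synthetic seed %d",
                                            spec$seed)),
    truth = data.frame(category = category[keep],
                       tree_id = tree_id[keep]),
    trajectory = traj,
    stem_map = cbind(tree_id = seq_len(spec$n_trees),
                     x = stems[, 1], y = stems[, 2]),
    ground_fun = function(x, y) gz(x, y),
    spec = spec), class = "forest_scene")
}

#' @export
print.forest_scene <- function(x, ...) {
  cat(sprintf("forest_scene: %d trees, %d points (seed %d)\n",
              x$spec$n_trees, npoints(x$cloud), x$spec$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Reference labeling from generator truth
#'
#' Converts a synthetic scene's per-point truth into the reference labeling
#' a manual segmentation would provide: trunk and crown points carry their
#' true tree id; ground, shrub and outlier points are excluded (label 0).
#'
#' @param scene a `forest_scene` from [simulate_forest()].
#' @return a list with `labels` (integer per scene point) and `stem_map`
#'   (true tree locations), usable as the `reference` of [match_trees()].
#' @export
truth_to_reference <- function(scene) {
  stopifnot(inherits(scene, "forest_scene"))
  lab <- ifelse(scene$truth$category %in% c("trunk", "crown"),
                scene$truth$tree_id, 0L)
  list(labels = as.integer(lab), stem_map = scene$stem_map)
}
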