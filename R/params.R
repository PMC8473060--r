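#' Preprocessing parameters
#'
#' Controls the trajectory-hull outlier gate, the morphological ground
#' filter, and DTM construction. Defaults are conventional values for
#' centimeter-accuracy terrestrial clouds in closed forest.
#'
#' @param hull_buffer meters; points within this distance outside the
#'   trajectory's convex hull are kept.
#' @param morph_window meters; width of the square structuring element of
#'   the grayscale opening applied to the minimum-z raster.
#' @param morph_height_tol meters; a point is ground iff its height above the
#'   opened surface is at most this.
#' @param idw_power inverse-distance weighting exponent.
#' @param idw_neighbors number of nearest ground points per DTM cell.
#' @param dtm_cell meters; DTM grid cell size.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(hull_buffer = 1, morph_window = 2,
                              morph_height_tol = 0.3, idw_power = 2,
                              idw_neighbors = 8, dtm_cell = 0.5) {
  p <- list(hull_buffer = hull_buffer, morph_window = morph_window,
            morph_height_tol = morph_height_tol, idw_power = idw_power,
            idw_neighbors = as.integer(idw_neighbors), dtm_cell = dtm_cell)
  if (p$hull_buffer < 0) stop("hull_buffer must be >= 0")
  for (nm in c("morph_window", "morph_height_tol", "idw_power",
               "idw_neighbors", "dtm_cell"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("%s must be strictly positive", nm))
  structure(p, class = "preprocess_params")
}

#' Segmentation parameters
#'
#' Parameters of the trunk detection, cylinder voxelization and merge/noise
#' stages. The defaults are the optimal setting found by the sensitivity
#' analysis on real backpack data: `eps_trunk = 0.1` m, `eps_cylinder = 0.9`
#' m and noise threshold `d* = 0.87` m.
#'
#' @param eps_trunk meters; DBSCAN radius for trunk-slab clustering (XY).
#' @param eps_cylinder meters; DBSCAN radius for per-cylinder 3D
#'   subclustering. Low values are intended, so surrounding crowns split
#'   into small subclusters rather than gluing to the stem.
#' @param min_points DBSCAN minimum neighbor count (self included) for the
#'   trunk step (`N_min`).
#' @param min_points_cyl DBSCAN minimum neighbor count for the per-cylinder
#'   step; permissive by default because deliberate oversegmentation is
#'   wanted there.
#' @param noise_threshold meters; discarded points farther than this from
#'   every segment become noise (`d*`). Strict comparison: a point at
#'   exactly `d*` is noise.
#' @param slab_zmin,slab_zmax meters, normalized heights; trunk-layer slab
#'   bounds (inclusive).
#' @param continuity_bin meters; z-histogram bin width for the vertical
#'   continuity test.
#' @param continuity_ground_max meters; a subcluster can only be
#'   ground-connected if its lowest occupied bin starts at or below this.
#' @param continuity_gap_bins a run of at least this many consecutive empty
#'   bins inside a subcluster's own vertical extent marks a discontinuity.
#' @param fp_retry logical; during validation matching, whether a reference
#'   tree retries the next-nearest segment after a false-positive verdict
#'   (default) or is declared a false negative immediately.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(eps_trunk = 0.1, eps_cylinder = 0.9, min_points = 40,
                       min_points_cyl = 10, noise_threshold = 0.87,
                       slab_zmin = 1.0, slab_zmax = 1.5,
                       continuity_bin = 0.25, continuity_ground_max = 0.5,
                       continuity_gap_bins = 2, fp_retry = TRUE) {
  p <- list(eps_trunk = eps_trunk, eps_cylinder = eps_cylinder,
            min_points = as.integer(min_points),
            min_points_cyl = as.integer(min_points_cyl),
            noise_threshold = noise_threshold,
            slab_zmin = slab_zmin, slab_zmax = slab_zmax,
            continuity_bin = continuity_bin,
            continuity_ground_max = continuity_ground_max,
            continuity_gap_bins = as.integer(continuity_gap_bins),
            fp_retry = isTRUE(fp_retry))
  if (p$eps_trunk <= 0) stop("eps_trunk must be > 0")
  if (p$eps_cylinder <= 0) stop("eps_cylinder must be > 0")
  if (p$min_points < 1L) stop("min_points must be >= 1")
  if (p$min_points_cyl < 1L) stop("min_points_cyl must be >= 1")
  if (p$noise_threshold <= 0) stop("noise_threshold must be > 0")
  if (p$slab_zmin >= p$slab_zmax) stop("slab_zmin must be < slab_zmax")
  if (p$continuity_bin <= 0) stop("continuity_bin must be > 0")
  if (p$continuity_ground_max <= 0) stop("continuity_ground_max must be > 0")
  structure(p, class = "seg_params")
}
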