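#' Match algorithm trees against a reference segmentation
#'
#' Implements the iterative reference-versus-algorithm matching procedure.
#' Reference trees are visited in ascending tree id. For reference tree R
#' with nearest reference neighbor R' (stem-to-stem XY distance), the
#' cluster proximity `d_min` is the mean distance from each point of R to
#' its nearest point of R'. The closest unconsumed algorithm segment whose
#' stem lies within `d_min` of R's stem is examined; with `N* = |segment|`,
#' `N1 = |R|`, `N2 = |R'|`:
#' \itemize{
#'   \item `N* > N1` and `N* >= N1 + N2`: the segment overlaps two or more
#'     real trees — false positive; the segment is consumed and (by
#'     default) R retries the next-nearest candidate;
#'   \item `N* > N1` and `N* < N1 + N2`: true positive;
#'   \item `N* <= N1`: true positive (the algorithm tree may be
#'     incomplete but is truly identified).
#' }
#' A reference tree with no remaining candidate within `d_min` is a false
#' negative. Consumed segments are never re-matched; segments never
#' examined stay `unmatched` and do not count as false positives.
#'
#' @param reference reference labeling: a list with `labels` (integer per
#'   cloud point, 0 = not a tree) and optionally `stem_map` (columns
#'   tree_id, x, y); see [truth_to_reference()]. Without a stem map, each
#'   tree's stem is the XY centroid of its lowest 0.5 m of points.
#' @param predicted a `stemseg` fit, or a list with `labels` and
#'   `tree_locations` in the same form.
#' @param cloud the [point_cloud()] both labelings refer to.
#' @param fp_retry after a false-positive verdict, try the next-nearest
#'   candidate (default); `FALSE` declares the reference tree a false
#'   negative immediately.
#' @return an object of class `match_outcome`: per-reference verdicts
#'   (with `d_min`), per-segment verdicts, and counts `n_tp`, `n_fp`,
#'   `n_fn`, `n_ref`.
#' @export
match_trees <- function(reference, predicted, cloud, fp_retry = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  ref_lab <- as.integer(reference$labels)
  if (length(ref_lab) != npoints(cloud))
    stop("match_trees: reference labeling does not cover the cloud (",
         length(ref_lab), " labels vs ", npoints(cloud), " points)")
  if (inherits(predicted, "stemseg"))
    predicted <- list(labels = predicted$labels,
                      tree_locations = predicted$tree_locations)
  pred_lab <- as.integer(predicted$labels)
  if (length(pred_lab) != npoints(cloud))
    stop("match_trees: predicted labeling does not cover the cloud")

  ref_ids <- sort(unique(ref_lab[ref_lab > 0L]))
  if (length(ref_ids) < 2L)
    stop("match_trees: at least 2 reference trees are required to define ",
         "d_min")
  ref_pts <- lapply(ref_ids, function(id)
    cloud$coords[ref_lab == id, , drop = FALSE])
  ref_stems <- stems_of(reference, ref_ids, ref_pts)

  pred_ids <- sort(unique(pred_lab[pred_lab > 0L]))
  pred_pts <- lapply(pred_ids, function(id)
    cloud$coords[pred_lab == id, , drop = FALSE])
  pred_stems <- stems_of(predicted, pred_ids, pred_pts,
                         map_name = "tree_locations")

  consumed <- rep(FALSE, length(pred_ids))
  seg_verdict <- rep("unmatched", length(pred_ids))
  verdict <- character(length(ref_ids))
  d_min_all <- numeric(length(ref_ids))
  matched_seg <- rep(NA_integer_, length(ref_ids))

  for (k in seq_along(ref_ids)) {
    dstem <- sqrt((ref_stems[, 1] - ref_stems[k, 1])^2 +
                  (ref_stems[, 2] - ref_stems[k, 2])^2)
    dstem[k] <- Inf
    kp <- which.min(dstem)
    d_min <- mean(nn_dist_cpp(ref_pts[[k]], ref_pts[[kp]]))
    d_min_all[k] <- d_min
    N1 <- nrow(ref_pts[[k]]); N2 <- nrow(ref_pts[[kp]])

    if (length(pred_ids)) {
      dseg <- sqrt((pred_stems[, 1] - ref_stems[k, 1])^2 +
                   (pred_stems[, 2] - ref_stems[k, 2])^2)
      cand <- order(dseg)
      cand <- cand[dseg[cand] <= d_min & !consumed[cand]]
    } else cand <- integer(0)

    verdict[k] <- "FN"
    for (s in cand) {
      Nstar <- nrow(pred_pts[[s]])
      if (Nstar > N1 && Nstar >= N1 + N2) {
        consumed[s] <- TRUE
        seg_verdict[s] <- "FP"
        if (!fp_retry) break
      } else {
        consumed[s] <- TRUE
        seg_verdict[s] <- "TP"
        verdict[k] <- "TP"
        matched_seg[k] <- pred_ids[s]
        break
      }
    }
  }

  structure(list(
    per_reference = data.frame(tree_id = ref_ids, verdict = verdict,
                               d_min = d_min_all,
                               matched_segment = matched_seg),
    per_segment = data.frame(tree_id = pred_ids, verdict = seg_verdict),
    n_tp = sum(verdict == "TP"),
    n_fn = sum(verdict == "FN"),
    n_fp = sum(seg_verdict == "FP"),
    n_ref = length(ref_ids)), class = "match_outcome")
}

# stems for a labeling: use the supplied stem map when present, else the
# XY centroid of each tree's lowest 0.5 m of points (the trunk beginning)
stems_of <- function(labeling, ids, pts, map_name = "stem_map") {
  m <- labeling[[map_name]]
  if (!is.null(m)) {
    m <- as.matrix(m)
    rows <- match(ids, m[, 1])
    if (!anyNA(rows)) return(m[rows, 2:3, drop = FALSE])
  }
  t(vapply(pts, function(p) {
    low <- p[, 3] <= min(p[, 3]) + 0.5
    colMeans(p[low, 1:2, drop = FALSE])
  }, numeric(2)))
}

#' @export
print.match_outcome <- function(x, ...) {
  cat(sprintf("match_outcome: %d reference trees -> %d TP, %d FN, %d FP\n",
              x$n_ref, x$n_tp, x$n_fn, x$n_fp))
  invisible(x)
}

#' Detection rate and error metrics
#'
#' Evaluates the detection rate `DR = NTP / NR`, the commission error
#' `E_COM = NFN / (NTP + NFN)` and the omission error
#' `E_OM = NFP / (NTP + NFP)` from matching counts. Zero-denominator cases
#' yield `NA` (an explicit undefined marker).
#'
#' @param outcome a `match_outcome` from [match_trees()], or a list with
#'   `n_tp`, `n_fn`, `n_fp` (and optionally `n_ref`).
#' @param n_ref number of reference trees; defaults to the outcome's.
#' @return an object of class `tree_metrics` with fields `dr`, `e_com`,
#'   `e_om` (fractions in `[0, 1]`) and the counts.
#' @export
segmentation_metrics <- function(outcome, n_ref = outcome$n_ref) {
  n_tp <- outcome$n_tp; n_fn <- outcome$n_fn; n_fp <- outcome$n_fp
  if (is.null(n_ref) || is.na(n_ref) || n_ref < 1)
    stop("segmentation_metrics: n_ref must be >= 1")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(dr = frac(n_tp, n_ref),
                 e_com = frac(n_fn, n_tp + n_fn),
                 e_om = frac(n_fp, n_tp + n_fp),
                 n_tp = n_tp, n_fn = n_fn, n_fp = n_fp, n_ref = n_ref),
            class = "tree_metrics")
}

#' @export
print.tree_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f%%",
                                                            100 * v)
  cat(sprintf("DR = %s  E_COM = %s  E_OM = %s  (TP %d, FN %d, FP %d of %d",
              pct(x$dr), pct(x$e_com), pct(x$e_om),
              x$n_tp, x$n_fn, x$n_fp, x$n_ref))
  cat(" reference trees)\n")
  invisible(x)
}

#' Parameter sensitivity sweep
#'
#' Re-runs the full pipeline over a factorial grid of `eps_trunk`,
#' `eps_cylinder` and `d*`, scoring each run against the reference
#' labeling. The default axes bracket the operating ranges found on real
#' data: `eps_trunk` up to its realistic cap of 0.5 m, `eps_cylinder`
#' around its optimal window of 0.8-1.0 m, `d*` around 0.87 m. A pipeline
#' failure at a grid point is recorded as a failed row, not an error.
#'
#' @param scene a `forest_scene`, or a list with `cloud`, `trajectory`
#'   (optional) and `reference` (labels + stem map).
#' @param eps_trunk,eps_cylinder,d_star numeric grid axes (meters).
#' @param params,pre base parameter sets; the swept values override them.
#' @return a data frame (class `stemseg_sweep`) with one row per
#'   combination: the three parameters, dr/e_com/e_om, counts and an `ok`
#'   flag; the argmax-DR row index is attached as attribute `"best"`.
#' @export
sensitivity_sweep <- function(scene,
                              eps_trunk = c(0.05, 0.1, 0.2, 0.35, 0.5),
                              eps_cylinder = c(0.4, 0.6, 0.8, 0.9, 1.0,
                                               1.2, 1.4),
                              d_star = c(0.3, 0.6, 0.87, 1.2, 1.5),
                              params = seg_params(),
                              pre = preprocess_params()) {
  if (inherits(scene, "forest_scene"))
    scene <- list(cloud = scene$cloud, trajectory = scene$trajectory,
                  reference = truth_to_reference(scene))
  if (!length(eps_trunk) || !length(eps_cylinder) || !length(d_star))
    stop("sensitivity_sweep: all grid axes must be non-empty")
  grid <- expand.grid(eps_trunk = eps_trunk, eps_cylinder = eps_cylinder,
                      d_star = d_star, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- params
    p$eps_trunk <- grid$eps_trunk[g]
    p$eps_cylinder <- grid$eps_cylinder[g]
    p$noise_threshold <- grid$d_star[g]
    res <- tryCatch({
      fit <- suppressWarnings(segment_trees(scene$cloud, scene$trajectory,
                                            params = p, pre = pre,
                                            keep_cloud = FALSE))
      m <- segmentation_metrics(match_trees(scene$reference, fit,
                                            scene$cloud,
                                            fp_retry = p$fp_retry))
      data.frame(grid[g, ], dr = m$dr, e_com = m$e_com, e_om = m$e_om,
                 n_tp = m$n_tp, n_fn = m$n_fn, n_fp = m$n_fp,
                 n_trees = fit$stage_counts$n_trees, ok = TRUE,
                 error = "")
    }, error = function(e)
      data.frame(grid[g, ], dr = NA_real_, e_com = NA_real_,
                 e_om = NA_real_, n_tp = NA_integer_, n_fn = NA_integer_,
                 n_fp = NA_integer_, n_trees = NA_integer_, ok = FALSE,
                 error = conditionMessage(e)))
    rows[[g]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- if (any(out$ok & !is.na(out$dr)))
    which(out$ok)[which.max(out$dr[out$ok])] else NA_integer_
  attr(out, "best") <- best
  class(out) <- c("stemseg_sweep", class(out))
  out
}

#' @export
print.stemseg_sweep <- function(x, ...) {
  cat(sprintf("sensitivity sweep: %d parameter combinations\n", nrow(x)))
  b <- attr(x, "best")
  if (!is.na(b)) {
    cat("best detection rate:\n")
    print.data.frame(x[b, c("eps_trunk", "eps_cylinder", "d_star", "dr",
                            "e_com", "e_om")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param outcome a `match_outcome` from [match_trees()].
#' @param path output JSON path.
#' @param metrics optional precomputed `tree_metrics`; computed from the
#'   outcome when omitted.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(outcome, path, metrics = NULL) {
  stopifnot(inherits(outcome, "match_outcome"))
  if (is.null(metrics)) metrics <- segmentation_metrics(outcome)
  report <- list(n_ref = outcome$n_ref, n_tp = outcome$n_tp,
                 n_fp = outcome$n_fp, n_fn = outcome$n_fn,
                 dr = metrics$dr, e_com = metrics$e_com,
                 e_om = metrics$e_om,
                 per_tree = outcome$per_reference)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
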