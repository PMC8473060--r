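---
title: "Individual tree segmentation from backpack LiDAR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual tree segmentation from backpack LiDAR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemseg)
```

## The problem

Ground-based (backpack or handheld) laser scanners see a forest from below:
stems and understorey are densely sampled while tree tops thin out, which is
the opposite of airborne LiDAR. Canopy-surface segmentation methods therefore
fail on such clouds, but the trunks themselves become an excellent handle —
every tree crosses a breast-height slab as a compact, dense cluster of
returns. `stemseg` implements a trunk-first pipeline around that observation:

1. **Outlier gate.** The scanner trajectory's convex hull defines the
   surveyed polygon; returns farther than `hull_buffer` outside it are
   range artifacts and are dropped.
2. **Height normalization.** A grayscale morphological opening of the
   minimum-z raster separates ground from vegetation; ground returns are
   interpolated by inverse-distance weighting (IDW) into a digital terrain
   model (DTM), and every point's z becomes its height above the bilinearly
   interpolated DTM.
3. **Trunk detection.** Points with normalized height in
   `[slab_zmin, slab_zmax]` are projected to XY and clustered with DBSCAN at
   radius `eps_trunk`, minimum neighbor count `min_points`. Each cluster's
   equal-weight center of mass — the arithmetic mean of member XY — is a
   tree location.
4. **Cylinder voxelization.** Each trunk's *candidate radius* is the
   distance to its nearest neighboring trunk. Trunks are visited in
   ascending radius order; the still-unclaimed points inside each trunk's
   infinite vertical cylinder are extracted and subclustered with a 3D
   DBSCAN at `eps_cylinder`, deliberately small so crown material from
   neighboring trees oversegments into small pieces rather than gluing to
   the stem. Claimed points leave the pool, so cylinder point sets are
   disjoint by construction; what no cylinder captures is the *discarded*
   set.
5. **Merge and noise filter.** Each subcluster's vertical point-density
   profile classifies it as *ground-connected* (it reaches the ground
   without a tall empty gap) or *floating*. Floating segments merge into
   the closest ground-connected segment by minimum 3D point-to-point
   distance. Discarded points whose distance to the closest segment is
   strictly below the noise threshold `d*` join that segment; the rest are
   noise (label 0).

Validation mirrors the field procedure: reference trees (manual
segmentation, or generator truth here) are matched to algorithm segments by
an iterative rule on point counts, yielding the detection rate
`DR = N_TP / N_R`, commission error `E_COM = N_FN / (N_TP + N_FN)` and
omission error `E_OM = N_FP / (N_TP + N_FP)`.

## Parameters

| parameter | unit | default | role and rationale |
|---|---|---|---|
| `eps_trunk` | m | 0.1 | DBSCAN radius of the trunk slab clustering. The optimal value found by sensitivity analysis on real backpack data; larger values merge neighboring stems (the dominant failure mode). Realistic ceiling 0.5 m. |
| `min_points` | count | 40 | Core threshold for trunk clusters. A 43,000 pts/s scanner puts hundreds of returns into a 0.5 m stem slab, so 40 rejects shrub wisps without losing stems. |
| `slab_zmin`, `slab_zmax` | m | 1.0, 1.5 | Trunk slab in normalized height: above most shrubs, below most crown bases, near breast height. Bounds inclusive. |
| `eps_cylinder` | m | 0.9 | 3D DBSCAN radius inside cylinders; optimal window 0.8–1.0 m. Small values are intended (oversegmentation is repaired by merging). |
| `min_points_cyl` | count | 10 | Permissive minimum for per-cylinder subclustering — small floating pieces are wanted. Kept independent of `min_points`. |
| `noise_threshold` (`d*`) | m | 0.87 | Discarded points strictly closer than this to a segment join it; at or beyond it they are noise. Optimal value from the same sensitivity analysis; forest-dependent. |
| `continuity_bin` | m | 0.25 | Bin width of the vertical density histogram (bins anchored at height 0). |
| `continuity_ground_max` | m | 0.5 | A ground-connected segment's lowest occupied bin must start at or below this. |
| `continuity_gap_bins` | bins | 2 | A run of this many empty bins inside a segment's extent is a discontinuity. |
| `hull_buffer` | m | 1 | Tolerance outside the trajectory hull. |
| `morph_window` | m | 2 | Structuring-element width of the opening; the raster sub-cell is `morph_window / 5` so a 5×5 element spans exactly the window. |
| `morph_height_tol` | m | 0.3 | Maximum height above the opened surface for a ground point. |
| `idw_power`, `idw_neighbors` | –, count | 2, 8 | Conventional IDW weights `1/d^2` over the 8 nearest ground points. |
| `dtm_cell` | m | 0.5 | DTM resolution; fine enough that bilinear interpolation tracks gentle terrain. |

The source the pipeline derives from specifies `eps_trunk`, `eps_cylinder`
and `d*`; every other default is this package's own choice, set once to
conventional values for centimeter-accuracy terrestrial clouds in closed
forest, and exposed in `preprocess_params()` / `seg_params()`.

## Design decisions in the open spots

* **Ground points are excluded before segmentation.** Cylinders are
  infinite in z, so keeping ground returns would hand every cylinder a
  ground-connected carpet that glues trees together and inflates per-tree
  point counts against any reference that (as manual segmentation does)
  excludes ground. The vegetation cloud is what gets voxelized; ground,
  hull-removed and noise points all carry label 0.
* **Iteration order** of the cylinders is ascending candidate radius (ties
  by trunk id): small cylinders claim their points before a large neighbor
  can swallow them. The candidate radius is the full nearest-neighbor
  distance, as defined; overlap between neighboring cylinders is resolved
  by pool removal, and contested points go to the earlier (smaller) one.
* **All ground-connected subclusters of a cylinder belong to that
  cylinder's tree.** A neighbor's near trunk half captured by the closed
  disk is legitimately ground-connected; the union is that tree's root
  segment. Shrubs inside a cylinder likewise fold into its tree rather
  than spawning phantom trees.
* **Border-point determinism.** DBSCAN border points join the cluster of
  their lowest-indexed core neighbor, clusters are numbered by ascending
  lowest core index, and neighbor counts include the point itself. The
  labeling is a pure function of the coordinates — no traversal-order
  dependence across platforms.
* **Single-trunk plots** have no nearest neighbor; the candidate radius
  falls back to the cloud's XY bounding-circle radius (the whole plot is
  one tree).
* **Matching after a false positive.** The procedure's source is silent on
  whether a reference tree keeps looking after its nearest candidate is
  declared FP; `match_trees()` retries the next-nearest unconsumed segment
  within `d_min` (switch `fp_retry = FALSE` for immediate FN). Algorithm
  segments never examined stay `unmatched` and are not counted as FP.
* **`d_min`** ("average of all the distances between the corresponding
  points") is operationalized as the directed mean nearest-neighbor
  distance from the reference tree to its closest reference neighbor —
  well-defined for unequal cluster sizes.
* **Strict threshold.** A discarded point at exactly `d*` is noise
  ("below a threshold distance" read literally); ties between segments
  break toward the lower tree id everywhere.

## The synthetic generator

Field clouds for this kind of survey are rarely deposited, so
`simulate_forest()` builds scenes with known truth: a sloped, noisy ground
plane; stems placed by rejection sampling with a minimum spacing; trunk
returns at radius `Normal(r, trunk_ring_sigma)` around the stem outline —
handheld scanners place returns both inside and outside the stem surface,
with density peaking at the outline; uniform-in-ellipsoid crowns; low shrub
blobs (below the trunk slab); far-range outliers in an annulus outside the
serpentine walking trajectory; and a distance-to-trajectory dropout (2 % per
meter, capped at 15 %) as a cheap occlusion stand-in.

Default scene: 20 trees in a 30 × 30 m plot, 4 m minimum spacing, stem radii
0.10–0.18 m (ring sigma 0.02 m), crown bases at 4–7 m, 4000 trunk + 800
crown returns per tree, 20 ground returns/m², six shrubs, 150 outliers —
about 10⁵ points, matching the per-slab return counts a 43,000 pts/s
scanner delivers.

What the generator does **not** emulate: ray-traced occlusion shadows,
beam divergence and footprint growth, multi-echo returns, leaning or forked
stems, branch structure, terrain breaklines, and registration drift. Tests
passing on these scenes show the algorithm's logic is implemented correctly
and behaves as designed under its stated assumptions (vertical, well-spaced
stems); they do not certify field performance, which in real stands is
driven by exactly the effects above.

## Numerical choices and degenerate inputs

* Cylinder membership and DBSCAN neighborhoods are closed (`<= eps`).
* IDW uses a source point directly when it sits within 1e-9 m of a cell
  center; every DTM cell is filled (no nodata after interpolation).
* Points outside the DTM extent normalize against the nearest cell and are
  reported; a collinear trajectory, an empty trunk slab, zero trunk
  clusters, duplicate trunk centroids, and a scene with no ground-connected
  segment each raise a named error rather than propagating nonsense.
* Metrics with zero denominators return `NA`, never `NaN` arithmetic.
* Continuity histogram bins are anchored at height 0 so the classification
  does not depend on a segment's own minimum.

## Problem sizes

The shipped tests run the full pipeline on the 20-tree default stand
(~110,000 points, about 7 s) plus smaller 3–6-tree stands for property
checks; DBSCAN is cross-checked against a brute-force reference on 50
random configurations of up to 500 points; `scripts/acceptance.R`
re-generates the default stand from a seed and recomputes every reported
number at run time.

## Known limitations

* Stems closer together than `eps_trunk` merge into one detected tree —
  the documented failure mode; `sensitivity_sweep()` quantifies it.
* Leaning trees violate the vertical-cylinder assumption; points of a
  strongly leaning crown end up with its upright neighbors.
* The morphological filter assumes terrain varies slowly within the
  2 m window; cliffs and walls would be classified as vegetation.
* LAS support is uncompressed LAS 1.2, point formats 0–3, with the tree id
  as a `tree_id` extra-bytes dimension; LAZ must be decompressed first.
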