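square_path <- function() trajectory(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10),
                                           1.7))

test_that("hull gate keeps inside and near-boundary points only", {
  traj <- square_path()
  cloud <- point_cloud(rbind(c(5, 5, 1), c(20, 5, 1), c(11.5, 5, 0)))
  kept <- hull_outlier_filter(cloud, traj, buffer = 2)
  expect_equal(attr(kept, "kept"), c(TRUE, FALSE, TRUE))
  # z plays no role
  cloud2 <- point_cloud(rbind(c(5, 5, 500), c(20, 5, -3)))
  expect_equal(attr(hull_outlier_filter(cloud2, traj, 2), "kept"),
               c(TRUE, FALSE))
})

test_that("hull gate matches a point-in-polygon + boundary-distance oracle", {
  set.seed(101)
  traj <- trajectory(cbind(runif(12, 2, 12), runif(12, 2, 12), 1.7))
  hull <- stemseg:::trajectory_hull(traj)
  cloud <- point_cloud(cbind(runif(1000, -2, 16), runif(1000, -2, 16),
                             runif(1000, 0, 5)))
  buffer <- 1.3
  kept <- attr(hull_outlier_filter(cloud, traj, buffer), "kept")

  inside <- mgcv::in.out(rbind(hull, hull[1, ]),
                         cloud$coords[, 1:2, drop = FALSE])
  seg_d <- function(p, a, b) { # point-to-segment distance
    ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t)); sqrt(sum((p - (a + t * ab))^2))
  }
  nv <- nrow(hull)
  bd <- vapply(seq_len(npoints(cloud)), function(i) {
    p <- cloud$coords[i, 1:2]
    min(vapply(seq_len(nv), function(e)
      seg_d(p, hull[e, ], hull[if (e == nv) 1 else e + 1, ]), 0))
  }, 0)
  expect_equal(kept, inside | bd <= buffer)
})

test_that("hull gate is idempotent and monotone in the buffer", {
  set.seed(102)
  traj <- square_path()
  cloud <- point_cloud(cbind(runif(500, -5, 15), runif(500, -5, 15), 0))
  k1 <- hull_outlier_filter(cloud, traj, 0.5)
  k1b <- hull_outlier_filter(k1, traj, 0.5)
  expect_equal(k1$coords, k1b$coords)
  prev <- rep(FALSE, 500)
  for (b in c(0, 0.5, 1, 2, 4)) {
    cur <- attr(hull_outlier_filter(cloud, traj, b), "kept")
    expect_true(all(cur[prev])) # retained sets nest
    prev <- cur
  }
})

test_that("collinear trajectories cannot form a survey polygon", {
  traj <- trajectory(cbind(0:3, 0:3, 1.7))
  cloud <- point_cloud(rbind(c(1, 1, 0)))
  expect_error(hull_outlier_filter(cloud, traj, 1), "collinear")
})

test_that("morphological filter: flat ground all ground, stems non-ground", {
  set.seed(103)
  flat <- point_cloud(cbind(runif(2000, 0, 20), runif(2000, 0, 20), 0))
  gf <- morphological_ground_filter(flat)
  expect_true(all(gf$is_ground))

  stem <- make_stem(10, 10, 400, z0 = 0.5, z1 = 5)
  cloud <- point_cloud(rbind(flat$coords, stem))
  gf2 <- morphological_ground_filter(cloud)
  tol <- preprocess_params()$morph_height_tol
  stem_part <- tail(gf2$is_ground, 400)
  expect_true(all(!stem_part[stem[, 3] > tol]))
  # ground/nonground is a partition
  expect_equal(npoints(gf2$ground) + npoints(gf2$nonground),
               npoints(cloud))
})

test_that("IDW DTM reproduces constant and symmetric fields, and the
           direct-summation formula", {
  pars <- preprocess_params(dtm_cell = 1)
  flat <- point_cloud(cbind(runif(200, 0, 10), runif(200, 0, 10), 5))
  dtm <- build_dtm(flat, pars)
  expect_equal(max(abs(dtm$z - 5)), 0)

  # cell center equidistant from z = 0 and z = 2
  two <- point_cloud(rbind(c(0, 0.5, 0), c(2, 0.5, 2)))
  dtm2 <- build_dtm(two, preprocess_params(dtm_cell = 1, idw_neighbors = 2),
                    extent = c(0.5, 1.5, 0, 1))
  expect_equal(as.numeric(dtm2$z), 1)

  set.seed(104)
  g <- point_cloud(cbind(runif(50, 0, 10), runif(50, 0, 10),
                         runif(50, 0, 3)))
  pars3 <- preprocess_params(dtm_cell = 0.5, idw_neighbors = 6,
                             idw_power = 2)
  dtm3 <- build_dtm(g, pars3)
  for (q in 1:10) {
    ix <- sample(nrow(dtm3$z), 1); iy <- sample(ncol(dtm3$z), 1)
    ctr <- dtm3$origin + (c(ix, iy) - 0.5) * dtm3$cell_size
    expect_equal(dtm3$z[ix, iy],
                 oracle_idw(g$coords[, 1:2], g$coords[, 3], ctr, 6, 2),
                 tolerance = 1e-9)
  }
  expect_error(build_dtm(point_cloud(matrix(numeric(0), 0, 3))), "empty")
})

test_that("height normalization subtracts the interpolated DTM", {
  pars <- preprocess_params(dtm_cell = 1)
  flat <- point_cloud(cbind(runif(300, 0, 10), runif(300, 0, 10), 5))
  dtm <- build_dtm(flat, pars)
  pt <- point_cloud(rbind(c(4.2, 6.1, 7)))
  expect_equal(normalize_heights(pt, dtm)$coords[, 3], 2,
               ignore_attr = TRUE)
  # point exactly at a cell center gets exactly that cell's elevation
  ctr <- dtm$origin + (c(3, 4) - 0.5) * dtm$cell_size
  pt2 <- point_cloud(rbind(c(ctr, 9)))
  expect_equal(normalize_heights(pt2, dtm)$coords[, 3],
               9 - dtm$z[3, 4], ignore_attr = TRUE)
  # XY and order are untouched
  set.seed(105)
  many <- point_cloud(cbind(runif(50, 0, 10), runif(50, 0, 10),
                            runif(50)))
  norm <- normalize_heights(many, dtm)
  expect_equal(norm$coords[, 1:2], many$coords[, 1:2])
})

test_that("planar terrain is recovered within the slope-resolution bound", {
  set.seed(106)
  n <- 8000
  x <- runif(n, 0, 20); y <- runif(n, 0, 20)
  ground <- point_cloud(cbind(x, y, 0.1 * x + 0.05 * y))
  pars <- preprocess_params(dtm_cell = 0.5)
  dtm <- build_dtm(ground, pars)
  norm <- normalize_heights(ground, dtm)
  inner <- x > 1 & x < 19 & y > 1 & y < 19 # away from extrapolation edge
  expect_lt(max(abs(norm$coords[inner, 3])), 2 * pars$dtm_cell * 0.1)
  # empirical ground height distribution centered at 0
  expect_lt(abs(mean(norm$coords[inner, 3])), 0.02)
})

test_that("DTM exports as an ESRI ASCII grid", {
  d <- withr::local_tempdir()
  flat <- point_cloud(cbind(runif(100, 0, 4), runif(100, 0, 4), 2))
  dtm <- build_dtm(flat, preprocess_params(dtm_cell = 1))
  f <- file.path(d, "dtm.asc")
  write_dtm_asc(dtm, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_match(hdr[5], "^cellsize 1")
  body <- utils::read.table(f, skip = 6)
  expect_equal(unname(as.matrix(body)),
               matrix(2, ncol(dtm$z), nrow(dtm$z)))
})
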