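seg <- function(id, idx, gc, stem = c(0, 0))
  stemseg:::make_segment(id, idx, gc, stem)

test_that("vertical continuity distinguishes rooted columns from blobs", {
  p <- seg_params()
  zcol <- seq(0.1, 5.0, by = 0.1) # every 0.25 m bin occupied
  cloud <- point_cloud(cbind(0, 0, c(zcol, seq(4, 6, by = 0.1))))
  expect_true(classify_continuity(cloud, seq_along(zcol), p))
  # floating: z in [4, 6] only, lowest bin far above ground
  expect_false(classify_continuity(cloud,
                                   length(zcol) + seq_len(21), p))
  # a 2-bin internal gap also floats the segment even if it starts low
  zgap <- c(0.1, 0.2, 1.0, 1.1) # bins 0 and 4: 3 empty bins between
  cloud2 <- point_cloud(cbind(0, 0, zgap))
  expect_false(classify_continuity(cloud2, 1:4, p))
})

test_that("continuity agrees with constructed ground truth", {
  set.seed(501)
  p <- seg_params()
  for (rep in 1:10) {
    rooted <- runif(1) < 0.5
    if (rooted) {
      z <- runif(300, 0, runif(1, 2, 6))
      cloud <- point_cloud(cbind(0, 0, z))
      expect_true(classify_continuity(cloud, 1:300, p))
    } else {
      zlo <- runif(1, 2, 4)
      z <- runif(300, zlo, zlo + 2)
      cloud <- point_cloud(cbind(0, 0, z))
      expect_false(classify_continuity(cloud, 1:300, p))
    }
  }
})

test_that("floating segments merge to the nearest ground-connected one", {
  set.seed(502)
  a <- make_stem(0, 0, 400); b <- make_stem(6, 0, 400)
  blob <- make_blob(0.65, 0, 4, 60, 0.3) # ~0.5 m from A, ~5 m from B
  cloud <- point_cloud(rbind(a, b, blob))
  segs <- list(seg(1, 1:400, TRUE, c(0, 0)),
               seg(2, 401:800, TRUE, c(6, 0)),
               seg(1, 801:860, FALSE, c(0, 0)))
  merged <- merge_floating(segs, cloud)
  expect_length(merged, 2L)
  expect_true(all(801:860 %in% merged[[1]]$point_indices))

  # exact tie goes to the lower tree id
  tie_cloud <- point_cloud(rbind(c(0, 0, 0), c(4, 0, 0), c(2, 0, 0)))
  tie <- merge_floating(list(seg(1, 1L, TRUE, c(0, 0)),
                             seg(2, 2L, TRUE, c(4, 0)),
                             seg(9, 3L, FALSE, c(0, 0))), tie_cloud)
  expect_true(3L %in% tie[[1]]$point_indices)
  expect_false(3L %in% tie[[2]]$point_indices)

  expect_error(merge_floating(list(seg(1, 1L, FALSE, c(0, 0))),
                              tie_cloud), "ground-connected")
})

test_that("random floating blobs match the min-pair-distance oracle", {
  set.seed(503)
  trees <- lapply(1:5, function(i) make_stem(6 * i, 0, 300))
  cloud_mat <- do.call(rbind, trees)
  segs <- lapply(1:5, function(i)
    seg(i, (i - 1) * 300 + 1:300, TRUE, c(6 * i, 0)))
  blob_list <- list()
  for (b in 1:30) {
    bl <- make_blob(runif(1, 4, 32), runif(1, -2, 2), runif(1, 2, 6),
                    20, 0.2)
    blob_list[[b]] <- bl
  }
  blobs <- do.call(rbind, blob_list)
  cloud <- point_cloud(rbind(cloud_mat, blobs))
  fsegs <- lapply(1:30, function(b)
    seg(100 + b, 1500 + (b - 1) * 20 + 1:20, FALSE, c(0, 0)))
  merged <- merge_floating(c(segs, fsegs), cloud)

  # oracle: per blob, tree minimizing min pairwise distance
  for (b in 1:30) {
    idx <- 1500 + (b - 1) * 20 + 1:20
    d <- vapply(1:5, function(i) {
      min(as.matrix(stats::dist(rbind(cloud$coords[idx, ],
                                      cloud$coords[(i - 1) * 300 + 1:300, ])
                                ))[1:20, -(1:20)])
    }, 0)
    want <- which.min(d)
    expect_true(all(idx %in% merged[[want]]$point_indices),
                label = sprintf("blob %d -> tree %d", b, want))
  }
})

test_that("discarded points join segments strictly below d* else noise", {
  cloud <- point_cloud(rbind(c(0, 0, 0), c(10, 0, 0),      # segments
                             c(0.5, 0, 0), c(10, 1.2, 0),  # discarded
                             c(0.87, 0, 0)))               # exactly d*
  segs <- list(seg(1, 1L, TRUE, c(0, 0)), seg(2, 2L, TRUE, c(10, 0)))
  asg <- assign_discarded(c(3L, 4L, 5L), segs, cloud, d_star = 0.87)
  expect_equal(asg$segment_of, c(1L, 0L, 0L)) # 1.2 m and exact-d* -> noise
  expect_equal(asg$noise, c(4L, 5L))
})

test_that("the noise set shrinks monotonically as d* grows", {
  set.seed(504)
  cloud <- point_cloud(rbind(make_stem(0, 0, 300),
                             cbind(runif(100, -3, 3), runif(100, -3, 3),
                                   runif(100, 0, 5))))
  segs <- list(seg(1, 1:300, TRUE, c(0, 0)))
  prev <- NULL
  for (ds in c(0.2, 0.5, 0.87, 1.5, 3)) {
    noise <- assign_discarded(301:400, segs, cloud, ds)$noise
    if (!is.null(prev)) expect_true(all(noise %in% prev))
    prev <- noise
  }
})

test_that("finalize relabels contiguously by stem position and conserves
           counts", {
  segs <- list(seg(7, c(1L, 2L), TRUE, c(5, 0)),
               seg(3, c(3L, 4L, 5L), TRUE, c(1, 0)))
  fin <- finalize_segmentation(6L, segs, noise = 6L)
  expect_equal(sort(unique(fin$labels)), c(0L, 1L, 2L))
  expect_equal(fin$labels, c(2L, 2L, 1L, 1L, 1L, 0L)) # x-ordered ids
  expect_equal(fin$tree_locations[, "tree_id"], c(1, 2),
               ignore_attr = TRUE)
  expect_equal(as.integer(table(fin$labels[fin$labels > 0])), c(3L, 2L))

  fin2 <- finalize_segmentation(5L, segs, noise = integer(0))
  expect_false(any(fin2$labels[c(1:5)] == 0L))
})
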