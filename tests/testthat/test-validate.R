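# Builds a flat scene with two reference trees of given sizes and one or
# more predicted segments of chosen sizes placed on top of reference tree 1.
match_fixture <- function(n1, n2, nstar, sep = 5) {
  pts1 <- cbind(runif(n1, -0.2, 0.2), runif(n1, -0.2, 0.2),
                runif(n1, 0, 4))
  pts2 <- cbind(sep + runif(n2, -0.2, 0.2), runif(n2, -0.2, 0.2),
                runif(n2, 0, 4))
  pred_parts <- lapply(seq_along(nstar), function(s)
    cbind(runif(nstar[s], -0.2, 0.2), runif(nstar[s], -0.2, 0.2),
          runif(nstar[s], 0, 4)))
  cloud <- point_cloud(rbind(pts1, pts2, do.call(rbind, pred_parts)))
  ref <- list(labels = c(rep(1L, n1), rep(2L, n2),
                         rep(0L, sum(nstar))),
              stem_map = cbind(tree_id = 1:2, x = c(0, sep), y = c(0, 0)))
  pl <- integer(sum(nstar))
  off <- 0
  for (s in seq_along(nstar)) { pl[off + seq_len(nstar[s])] <- s
                                off <- off + nstar[s] }
  pred <- list(labels = c(rep(0L, n1 + n2), pl),
               tree_locations = cbind(tree_id = seq_along(nstar), x = 0,
                                      y = 0))
  list(cloud = cloud, ref = ref, pred = pred)
}

test_that("matching applies the N*/N1/N2 comparison rules", {
  set.seed(601)
  # N* = 50, N1 = 30, N2 = 25: 50 > 30 and 50 < 55 -> TP
  f <- match_fixture(30, 25, 50)
  out <- match_trees(f$ref, f$pred, f$cloud)
  expect_equal(out$per_reference$verdict[1], "TP")
  expect_equal(out$n_tp, 1L)

  # N* = 60 >= 55 -> FP, and with no remaining candidate tree 1 is FN
  f2 <- match_fixture(30, 25, 60)
  out2 <- match_trees(f2$ref, f2$pred, f2$cloud)
  expect_equal(out2$per_reference$verdict[1], "FN")
  expect_equal(out2$n_fp, 1L)

  # N* = 20 <= N1 = 30 -> TP (incomplete but truly identified)
  f3 <- match_fixture(30, 25, 20)
  out3 <- match_trees(f3$ref, f3$pred, f3$cloud)
  expect_equal(out3$per_reference$verdict[1], "TP")
})

test_that("after an FP the next-nearest candidate is retried (and the
           consumed segment never re-matched)", {
  set.seed(602)
  # one oversized segment (FP) plus one correct segment on tree 1
  f <- match_fixture(30, 25, c(60, 28))
  out <- match_trees(f$ref, f$pred, f$cloud)
  expect_equal(out$n_fp, 1L)
  expect_equal(out$per_reference$verdict[1], "TP")
  expect_equal(sort(out$per_segment$verdict), c("FP", "TP"))

  # immediate-FN mode stops at the first FP
  out2 <- match_trees(f$ref, f$pred, f$cloud, fp_retry = FALSE)
  expect_equal(out2$per_reference$verdict[1], "FN")

  expect_error(
    match_trees(list(labels = rep(1L, npoints(f$cloud))), f$pred,
                f$cloud), "2 reference trees")
})

test_that("metric formulas are exact rational fractions", {
  m <- segmentation_metrics(list(n_tp = 8, n_fn = 2, n_fp = 1), n_ref = 10)
  expect_identical(m$dr, 0.8)
  expect_identical(m$e_com, 0.2)
  expect_equal(m$e_om, 1 / 9, tolerance = 1e-15)

  set.seed(603)
  for (rep in 1:20) {
    n_tp <- sample(0:50, 1); n_fn <- sample(0:50, 1)
    n_fp <- sample(0:50, 1); n_ref <- sample(1:100, 1)
    m <- segmentation_metrics(list(n_tp = n_tp, n_fn = n_fn, n_fp = n_fp),
                              n_ref = n_ref)
    # equals the correctly-rounded rational value, bit for bit
    expect_identical(m$dr, n_tp / n_ref)
    if (n_tp + n_fn > 0)
      expect_identical(m$e_com, n_fn / (n_tp + n_fn))
    else expect_true(is.na(m$e_com))
    if (n_tp + n_fp > 0)
      expect_identical(m$e_om, n_fp / (n_tp + n_fp))
    else expect_true(is.na(m$e_om))
  }
  expect_error(segmentation_metrics(list(n_tp = 1, n_fn = 0, n_fp = 0),
                                    n_ref = 0), "n_ref")
})

test_that("dr + e_com = 1 whenever every reference tree is verdicted", {
  set.seed(604)
  f <- match_fixture(30, 25, c(28, 24))
  out <- match_trees(f$ref, f$pred, f$cloud)
  expect_equal(out$n_tp + out$n_fn, out$n_ref)
  m <- segmentation_metrics(out)
  expect_equal(m$dr + m$e_com, 1)
})

test_that("metrics are invariant to rigid XY motion of the scene", {
  set.seed(605)
  f <- match_fixture(40, 35, c(38, 60))
  base <- segmentation_metrics(match_trees(f$ref, f$pred, f$cloud))
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- f$cloud$coords
  rot[, 1:2] <- rot[, 1:2] %*% R + rep(c(12, -7), each = nrow(rot))
  move_map <- function(m) { m[, 2:3] <- m[, 2:3] %*% R +
                              rep(c(12, -7), each = nrow(m)); m }
  ref2 <- list(labels = f$ref$labels, stem_map = move_map(f$ref$stem_map))
  pred2 <- list(labels = f$pred$labels,
                tree_locations = move_map(f$pred$tree_locations))
  moved <- segmentation_metrics(match_trees(ref2, pred2,
                                            point_cloud(rot)))
  expect_equal(moved$dr, base$dr)
  expect_equal(moved$e_com, base$e_com)
  expect_equal(moved$e_om, base$e_om)
})

test_that("a degenerate 1x1x1 sweep equals a direct pipeline run", {
  set.seed(606)
  sc <- toy_two_tree_scene(seed = 606)
  tab <- sensitivity_sweep(sc, eps_trunk = 0.1, eps_cylinder = 0.9,
                           d_star = 0.87)
  expect_equal(nrow(tab), 1L)
  expect_true(tab$ok)
  fit <- suppressWarnings(segment_trees(sc$cloud, sc$trajectory))
  m <- segmentation_metrics(match_trees(sc$reference, fit, sc$cloud))
  expect_equal(tab$dr, m$dr)
  expect_equal(tab$e_com, m$e_com)
  expect_equal(tab$e_om, m$e_om)
  expect_equal(attr(tab, "best"), 1L)
})

test_that("trunk merging at large eps_trunk degrades the detection rate", {
  set.seed(607)
  sc <- toy_two_tree_scene(spacing = 0.5, seed = 607)
  tab <- sensitivity_sweep(sc, eps_trunk = c(0.1, 0.5),
                           eps_cylinder = 0.9, d_star = 0.87)
  dr_small <- tab$dr[tab$eps_trunk == 0.1]
  dr_large <- tab$dr[tab$eps_trunk == 0.5]
  expect_true(dr_large <= dr_small)
})

test_that("validation reports serialize to JSON", {
  set.seed(608)
  f <- match_fixture(30, 25, 28)
  out <- match_trees(f$ref, f$pred, f$cloud)
  d <- withr::local_tempdir()
  p <- file.path(d, "report.json")
  write_validation_report(out, p)
  rep <- jsonlite::read_json(p)
  expect_equal(rep$n_ref, 2L)
  expect_equal(rep$dr, out$n_tp / out$n_ref)
  expect_length(rep$per_tree, 2L)
})
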