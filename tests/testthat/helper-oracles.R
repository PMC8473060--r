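# Independent oracles and small scene builders shared across tests.

# Brute-force DBSCAN: distance matrix + graph components over core points.
# Same semantics as dbscan(): neighbor counts include self, clusters are
# numbered by ascending lowest core index, border points join the cluster
# of their lowest-indexed core neighbor.
oracle_dbscan <- function(pts, eps, min_points) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  core <- rowSums(d <= eps) >= min_points
  labels <- integer(n)
  if (any(core)) {
    core_idx <- which(core)
    adj <- d[core_idx, core_idx, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    first <- tapply(core_idx, comp, min)
    renum <- as.integer(rank(first))
    labels[core_idx] <- renum[comp]
    for (i in which(!core)) {
      nb <- core_idx[d[i, core_idx] <= eps]
      if (length(nb)) labels[i] <- labels[min(nb)]
    }
  }
  labels
}

# Direct-summation IDW at a single query point.
oracle_idw <- function(gxy, gz, q, k, power) {
  d <- sqrt((gxy[, 1] - q[1])^2 + (gxy[, 2] - q[2])^2)
  o <- order(d)[seq_len(min(k, length(d)))]
  if (d[o[1]] < 1e-9) return(gz[o[1]])
  w <- 1 / d[o]^power
  sum(w * gz[o]) / sum(w)
}

# A vertical stem column: Gaussian ring of radius r around (cx, cy),
# heights uniform on [z0, z1].
make_stem <- function(cx, cy, n, r = 0.15, sigma = 0.02, z0 = 0, z1 = 5) {
  th <- runif(n, 0, 2 * pi)
  rr <- rnorm(n, r, sigma)
  cbind(cx + rr * cos(th), cy + rr * sin(th), runif(n, z0, z1))
}

# A compact blob (ball) of points.
make_blob <- function(cx, cy, cz, n, r = 0.4) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3) * r
  cbind(cx + u[, 1], cy + u[, 2], cz + u[, 3])
}

# Square trajectory around a plot.
square_traj <- function(xmin, xmax, ymin, ymax, z = 1.7, step = 0.5) {
  w <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax),
             c(xmin, ymin))
  pos <- do.call(rbind, lapply(seq_len(4), function(k) {
    a <- w[k, ]; b <- w[k + 1, ]
    tt <- seq(0, 1, length.out = max(2, ceiling(sqrt(sum((b - a)^2)) /
                                                  step)))
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }))
  trajectory(cbind(pos, z))
}

# A tiny fully-constructed two-tree scene on flat ground, with reference
# labels: ground + two stems with small crown blobs.
toy_two_tree_scene <- function(spacing = 6, n_stem = 3000, n_crown = 300,
                               n_ground = 3000, seed = 5) {
  set.seed(seed)
  gx <- runif(n_ground, 0, 14); gy <- runif(n_ground, 0, 14)
  ground <- cbind(gx, gy, rnorm(n_ground, 0, 0.01))
  s1 <- make_stem(4, 7, n_stem); s2 <- make_stem(4 + spacing, 7, n_stem)
  c1 <- make_blob(4, 7, 5.8, n_crown, 1.2)
  c2 <- make_blob(4 + spacing, 7, 5.8, n_crown, 1.2)
  cloud <- point_cloud(rbind(ground, s1, c1, s2, c2))
  ref <- c(rep(0L, n_ground), rep(1L, n_stem), rep(1L, n_crown),
           rep(2L, n_stem), rep(2L, n_crown))
  list(cloud = cloud,
       trajectory = square_traj(0.5, 13.5, 0.5, 13.5),
       reference = list(labels = ref,
                        stem_map = cbind(tree_id = 1:2,
                                         x = c(4, 4 + spacing),
                                         y = c(7, 7))))
}

# Small fast forest spec for property tests.
small_forest <- function(seed, n_trees = 6) {
  forest_spec(n_trees = n_trees, plot_size = c(18, 18), min_spacing = 4,
              trunk_points = 1500, crown_points = 400,
              ground_point_density = 8, n_shrubs = 2, shrub_points = 80,
              n_outliers = 40, seed = seed)
}
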