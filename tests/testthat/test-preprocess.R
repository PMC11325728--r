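test_that("SOR removes a gross outlier and matches the brute-force oracle", {
  set.seed(21)
  ball <- point_cloud(rnorm(200, sd = 0.003), rnorm(200, sd = 0.003),
                      rnorm(200, sd = 0.003))
  cloud <- dplyr::bind_rows(ball, point_cloud(10, 0, 0))
  out <- sor_filter(cloud, n_neighbors = 20, std_ratio = 2.5)
  expect_false(any(out$x == 10))
  expect_gte(nrow(out), 195)
  keep <- bf_sor_keep(cloud, 20, 2.5)
  expect_equal(nrow(out), sum(keep))
  expect_equal(out$x, cloud$x[keep])
})

test_that("SOR keeps every point when all neighborhoods are identical", {
  theta <- 2 * pi * (0:59) / 60
  cloud <- point_cloud(cos(theta), sin(theta), 0)  # fully symmetric
  out <- sor_filter(cloud, 6, 2.5)
  expect_equal(nrow(out), nrow(cloud))
})

test_that("SOR agrees with the oracle under point duplication", {
  set.seed(22)
  cloud <- point_cloud(runif(300), runif(300), runif(300, 0, 0.2))
  dup <- dplyr::bind_rows(cloud, cloud)
  out <- sor_filter(dup, 10, 2)
  keep <- bf_sor_keep(dup, 10, 2)
  expect_equal(nrow(out), sum(keep))
  expect_equal(out$x, dup$x[keep])
  # survivors nearly coincide with the original cloud's survivors (the
  # statistic shifts slightly because each duplicate contributes a
  # zero-distance neighbor)
  orig <- sor_filter(cloud, 10, 2)
  k1 <- paste(orig$x, orig$y)
  k2 <- unique(paste(out$x, out$y))
  expect_gte(length(intersect(k1, k2)) / length(union(k1, k2)), 0.95)
})

test_that("SOR warns and returns small clouds unchanged", {
  small <- point_cloud(1:5, 1:5, 0)
  expect_warning(out <- sor_filter(small, 20), "unchanged")
  expect_equal(nrow(out), 5)
})

test_that("min-distance subsampling satisfies both post conditions", {
  near <- point_cloud(c(0, 0.001), c(0, 0), c(0, 0))
  expect_equal(nrow(subsample_min_distance(near, 0.005)), 1)

  g <- expand.grid(x = seq(0, 0.1, by = 0.01), y = seq(0, 0.1, by = 0.01))
  grid_cloud <- point_cloud(g$x, g$y, 0)
  expect_equal(nrow(subsample_min_distance(grid_cloud, 0.005)), nrow(grid_cloud))

  set.seed(23)
  cloud <- point_cloud(runif(10000, 0, 0.1), runif(10000, 0, 0.1),
                       runif(10000, 0, 0.1))
  kept <- subsample_min_distance(cloud, 0.005)
  km <- as.matrix(kept[, c("x", "y", "z")])
  d <- bf_cross_dist(km, km)
  diag(d) <- Inf
  expect_gte(min(d), 0.005)               # retained pairs are >= d apart
  removed <- dplyr::anti_join(cloud, kept, by = c("x", "y", "z"))
  expect_lt(max(bf_nn_dist(as.matrix(removed[, c("x", "y", "z")]), km)), 0.005)
  # idempotence
  again <- subsample_min_distance(kept, 0.005)
  expect_equal(nrow(again), nrow(kept))
})

test_that("DTM reconstruction recovers flat and tilted ground", {
  set.seed(24)
  flat <- point_cloud(runif(5000, 0, 5), runif(5000, 0, 3), 0.5)
  dtm <- reconstruct_dtm(flat)
  expect_true(all(abs(dtm$elevations - 0.5) < 1e-12))

  x <- runif(40000, 0, 10); y <- runif(40000, 0, 5)
  tilted <- point_cloud(x, y, 0.01 * x)
  dtm2 <- reconstruct_dtm(tilted)
  qx <- runif(200, 0.3, 9.7); qy <- runif(200, 0.3, 4.7)
  expect_lt(max(abs(terrain_height(dtm2, qx, qy) - 0.01 * qx)), 0.001)

  expect_error(reconstruct_dtm(point_cloud()), "insufficient terrain data")
})

test_that("DTM ignores canopy blobs over well-sampled ground", {
  set.seed(25)
  x <- runif(60000, 0, 10); y <- runif(60000, 0, 5)
  ground <- point_cloud(x, y, 0.01 * x)
  blob <- function(cx, cy) {
    point_cloud(rnorm(2000, cx, 0.3), rnorm(2000, cy, 0.2),
                runif(2000, 0.5, 1) + 0.01 * cx)
  }
  cloud <- dplyr::bind_rows(ground, blob(3, 2), blob(7, 3))
  dtm <- reconstruct_dtm(cloud)
  # query points away from the canopy footprints
  qx <- c(1, 5, 9, 1.5, 8.6); qy <- c(1, 0.7, 1, 4.2, 4.4)
  expect_lt(max(abs(terrain_height(dtm, qx, qy) - 0.01 * qx)), 0.02)
})

test_that("DTM error grows with occlusion strength", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 5, replicate_a_sd = 0)
  terr <- generate_terrain(lay, seed = 5)
  errs <- vapply(c(0.1, 0.5, 0.9), function(occ) {
    sp <- session_spec(dap = 84, noise_sd = 0.005, outlier_fraction = 0,
                       occlusion_strength = occ, seed = 11)
    s <- generate_session_cloud(lay, asg, sp, terr, density = 2000,
                                ground_spacing = 0.1)
    dtm <- reconstruct_dtm(s$cloud)
    tp <- terrain_points(dtm)
    mean(abs(tp$z - terrain_height(terr, tp$x, tp$y)))
  }, numeric(1))
  expect_false(is.unsorted(errs))
})

test_that("height normalization subtracts the terrain and is idempotent on zero", {
  set.seed(26)
  cloud <- point_cloud(runif(3000, 0, 5), runif(3000, 0, 3), 0)
  cloud$z <- 0.3 + 0.02 * cloud$x
  dtm <- reconstruct_dtm(cloud)
  norm <- normalize_heights(cloud, dtm)
  expect_lt(max(abs(norm$z)), 0.002)

  zero <- terrain_model(c(-1, -1), 0.5, matrix(0, 20, 20))
  once <- normalize_heights(cloud, zero)
  twice <- normalize_heights(once, zero)
  expect_identical(once$z, twice$z)

  outside <- point_cloud(100, 100, 1)
  expect_warning(normalize_heights(outside, zero), "extrapolation")
})

test_that("normalized canopy height matches the simulator closed form", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 8, replicate_a_sd = 0)
  terr <- generate_terrain(lay, seed = 8)
  sp <- session_spec(dap = 77, noise_sd = 0.003, outlier_fraction = 0,
                     occlusion_strength = 0.2, seed = 2)
  s <- generate_session_cloud(lay, asg, sp, terr, density = 2000,
                              ground_spacing = 0.1)
  # denoise + thin, then normalize against the known terrain surface
  cl <- subsample_min_distance(sor_filter(s$cloud), 0.005)
  norm <- normalize_heights(cl, terr)
  grid <- layout_plot_grid(lay, genotypes = asg)
  tt <- extract_traits(norm, grid, dap = 77)
  truth <- s$truth$plots
  err <- tt$ch_max - truth$ch[match(tt$plot_id, truth$plot_id)]
  expect_lt(max(abs(err)), 0.02)
})
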