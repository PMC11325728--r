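test_that("ICP recovers an exact rigid offset of an irregular surface", {
  ref <- surface_cloud(3000, seed = 31)
  src <- ref
  src$x <- src$x + 0.1; src$y <- src$y + 0.1; src$z <- src$z + 0.02
  res <- icp_align_terrain(src, ref)
  expect_lt(res$rms, 0.001)
  expect_lt(max(abs(res$transform$translation + c(0.1, 0.1, 0.02))), 0.001)

  same <- icp_align_terrain(ref, ref)
  expect_lt(same$rms, 1e-9)
  expect_lt(max(abs(same$transform$rotation - diag(3))), 1e-9)

  expect_error(icp_align_terrain(point_cloud(1:5, 1:5, 0), ref), "at least 100")
})

test_that("BEV centroids land on the true plot centers of a clean session", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 5, replicate_a_sd = 0)
  terr <- generate_terrain(lay, seed = 5)
  sp <- session_spec(dap = 77, noise_sd = 0, outlier_fraction = 0,
                     occlusion_strength = 0, seed = 3)
  s <- generate_session_cloud(lay, asg, sp, terr, density = 5000,
                              ground_spacing = 0.1)
  cn <- bev_extract_centroids(normalize_heights(s$cloud, terr),
                              grid_resolution = 0.05)
  truth <- s$truth$plots
  d <- sqrt(outer(truth$centroid_x, cn$x, "-")^2 +
              outer(truth$centroid_y, cn$y, "-")^2)
  expect_true(all(apply(d, 1, min) <= 0.05))
})

test_that("BEV rejects clusters misaligned with the row axis and empty masks", {
  set.seed(32)
  strip <- function(cx, cy, lx, ly, n = 4000) {
    point_cloud(runif(n, cx - lx / 2, cx + lx / 2),
                runif(n, cy - ly / 2, cy + ly / 2), runif(n, 0.5, 1))
  }
  plots <- dplyr::bind_rows(strip(2, 1, 2.5, 1), strip(6, 1, 2.5, 1),
                            strip(10, 1, 2.5, 1))
  weed <- strip(6, 4, 0.8, 2.6)  # elongated 90 degrees to the row axis
  cn <- bev_extract_centroids(dplyr::bind_rows(plots, weed),
                              grid_resolution = 0.05, row_axis_bearing = 0)
  expect_equal(nrow(cn), 3)
  expect_true(all(abs(cn$y - 1) < 0.2))

  bare <- point_cloud(runif(500), runif(500), 0.0)
  expect_error(bev_extract_centroids(bare), "BEV extraction failed")
})

test_that("mutual nearest-neighbor matching excludes missing centroids", {
  grid <- expand.grid(x = (0:3) * 4.57, y = (0:2) * 1.83)
  ref <- tibble::tibble(x = grid$x, y = grid$y)
  expect_equal(match_centroids_knn(ref, ref)$k, 12)
  expect_equal(match_centroids_knn(ref, ref)$ref_idx,
               match_centroids_knn(ref, ref)$src_idx)

  src <- ref[-5, ]
  m <- match_centroids_knn(src, ref, 0.9)
  expect_equal(m$k, 11)
  expect_false(5 %in% m$ref_idx)

  shifted <- ref
  shifted$x <- shifted$x + 0.3
  m2 <- match_centroids_knn(shifted, ref, 0.9)
  expect_equal(m2$k, 12)
  expect_equal(m2$src[, 1] - m2$ref[, 1], rep(0.3, 12), tolerance = 1e-12)

  expect_error(match_centroids_knn(ref[1:2, ], ref[10:12, ], 0.9),
               "insufficient correspondences")
})

test_that("Procrustes alignment is exact on identity and pure translation", {
  grid <- as.matrix(expand.grid(x = (0:3) * 4.57, y = (0:2) * 1.83))
  same <- procrustes_align(make_pairs(grid, grid))
  expect_equal(c(same$tx, same$ty, same$theta), c(0, 0, 0))

  shifted <- sweep(grid, 2, c(0.5, 0.25), "-")
  tr <- procrustes_align(make_pairs(grid, shifted))
  expect_identical(tr$theta, 0)   # cross-product sum is exactly zero
  expect_equal(c(tr$tx, tr$ty), c(0.5, 0.25), tolerance = 1e-12)
})

test_that("Procrustes recovers a known rotation + shift within 1e-9 SSD", {
  ref <- as.matrix(expand.grid(x = (0:3) * 4.57, y = (0:2) * 1.83))
  theta <- -2 * pi / 180
  ctr <- colMeans(ref)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  src <- sweep(sweep(ref, 2, ctr) %*% t(rot), 2, ctr + c(0.30, -0.15), "+")
  tf <- procrustes_align(make_pairs(ref, src))
  expect_lt(ssd2d(ref, src, tf), 1e-18)
  oracle <- bf_procrustes(ref, src)
  expect_lt(abs(ssd2d(ref, src, tf) - ssd2d(ref, src, oracle)), 1e-9)
})

test_that("Procrustes is optimal on a theta grid and rotation-equivariant", {
  set.seed(33)
  for (rep in 1:10) {
    k <- sample(4:12, 1)
    ref <- cbind(runif(k, 0, 20), runif(k, 0, 8))
    src <- ref + matrix(rnorm(2 * k, sd = 0.05), k, 2)
    tf <- procrustes_align(make_pairs(ref, src))
    best <- ssd2d(ref, src, tf)
    for (th in seq(-0.05, 0.05, by = 1e-3)) {
      cr <- colMeans(ref); cs <- colMeans(src)
      ct <- cos(th); st <- sin(th)
      cand <- transform2d(cr[1] - (ct * cs[1] - st * cs[2]),
                          cr[2] - (st * cs[1] + ct * cs[2]), th)
      expect_lte(best, ssd2d(ref, src, cand) + 1e-12)
    }
    # pre-rotating both sets by a common angle leaves the residual unchanged
    phi <- runif(1, -pi, pi)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    tf2 <- procrustes_align(make_pairs(ref %*% t(rot), src %*% t(rot)))
    expect_equal(ssd2d(ref %*% t(rot), src %*% t(rot), tf2), best,
                 tolerance = 1e-9)
  }
})

test_that("degenerate centroid sets fall back to translation with a warning", {
  ref <- rbind(c(0, 0), c(0, 0))
  src <- rbind(c(1, 1), c(1, 1))
  expect_warning(tf <- procrustes_align(make_pairs(ref, src)), "degenerate")
  expect_equal(tf$theta, 0)
  expect_equal(c(tf$tx, tf$ty), c(-1, -1))
})

test_that("two-phase registration refines a synthetic session pair", {
  lay <- field_layout(n_rows = 4, plots_per_row = 6)
  panel <- cotton_genotypes()[c(1, 3, 5, 7, 9, 11), ]
  asg <- assign_genotypes(lay, panel, seed = 9)
  series <- generate_timeseries(lay, asg, daps = c(49, 62), seed = 9,
                                occlusion_strengths = c(0.2, 0.4),
                                density = 1500, ground_spacing = 0.12)
  inits <- coarse_pose_guesses(series, seed = 9)
  reg <- register_series(series, inits = inits)
  expect_equal(reg$phases, c("reference", "refined"))
  ev <- evaluate_series(series, reg, max_points = 20000)
  expect_lt(ev$hausdorff_final, ev$hausdorff_phase1)
  expect_lt(ev$hausdorff_final, 0.05)

  # identical clouds register to the identity within numerical noise
  pp <- reg$preprocessed[[1]]
  self <- register_pair(pp$raw, pp$raw, pp$terrain, pp$terrain)
  expect_lt(max(abs(transform_matrix(self$transform) - diag(4))), 1e-6)
})

test_that("global renormalization is idempotent for the reference session", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 3)
  terr <- generate_terrain(lay, seed = 3)
  s <- generate_session_cloud(lay, asg, session_spec(dap = 60, seed = 2), terr,
                              density = 500)
  pp <- preprocess_session(s$cloud)
  out <- global_renormalize(list(pp$raw), pp$terrain)
  expect_equal(out[[1]]$z, normalize_heights(pp$raw, pp$terrain)$z)
})

test_that("Procrustes rotation agrees with an independent implementation", {
  ref <- as.matrix(expand.grid(x = (0:3) * 4.57, y = (0:2) * 1.83))
  theta <- 1.5 * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  src <- sweep(ref %*% t(rot), 2, c(0.2, -0.1), "+")
  ours <- procrustes_align(make_pairs(ref, src))
  vg <- vegan::procrustes(ref, src, scale = FALSE)
  expect_equal(ours$theta, atan2(vg$rotation[1, 2], vg$rotation[1, 1]),
               tolerance = 1e-9)
})
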