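test_that("flat terrain limit and per-seed determinism", {
  lay <- tiny_layout()
  flat <- generate_terrain(lay, seed = 3, relief_amplitude = 0)
  expect_true(all(flat$elevations == 0))
  a <- generate_terrain(lay, seed = 11, relief_amplitude = 0.3)
  b <- generate_terrain(lay, seed = 11, relief_amplitude = 0.3)
  expect_identical(a$elevations, b$elevations)
  c_ <- generate_terrain(lay, seed = 12, relief_amplitude = 0.3)
  expect_false(identical(a$elevations, c_$elevations))
})

test_that("terrain relief is bounded by twice the amplitude and non-flat", {
  lay <- tiny_layout()
  tm <- generate_terrain(lay, seed = 7, relief_amplitude = 0.4)
  ext <- tls4d:::layout_extent(lay, margin = 1)
  xs <- seq(ext["xmin"], ext["xmax"], by = 0.01)
  ys <- seq(ext["ymin"], ext["ymax"], by = 0.01)
  z <- terrain_height(tm, rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  expect_lte(diff(range(z)), 0.8)
  expect_gt(diff(range(z)), 0)
})

test_that("session clouds honor the logistic growth closed form", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 2, replicate_a_sd = 0)
  terr <- generate_terrain(lay, seed = 2)

  # sigmoid lower tail: far before inflection the canopy is < 5% of A
  s0 <- generate_session_cloud(lay, asg, session_spec(dap = 0, seed = 1), terr,
                               density = 800)
  expect_true(all(s0$truth$plots$ch <= 0.05 * asg$A_ch[match(
    s0$truth$plots$plot_id, asg$plot_id)]))

  # clean session: max canopy height above local terrain equals the curve
  sp <- session_spec(dap = 70, noise_sd = 0, outlier_fraction = 0,
                     occlusion_strength = 0, seed = 5)
  s <- generate_session_cloud(lay, asg, sp, terr, density = 800)
  norm <- normalize_heights(s$cloud, terr)
  for (pid in asg$plot_id) {
    got <- max(norm$z[norm$plot_id == pid & norm$kind == "canopy"])
    want <- s$truth$plots$ch[s$truth$plots$plot_id == pid]
    expect_equal(got, want, tolerance = 1e-9)
  }
  # emitted truth equals the logistic closed form to machine precision
  i <- match(s$truth$plots$plot_id, asg$plot_id)
  expect_equal(s$truth$plots$ch,
               asg$A_ch[i] / (1 + exp(-asg$k_ch[i] * (70 - asg$Ti_ch[i]))),
               tolerance = 1e-12)
})

test_that("full occlusion removes every under-canopy terrain return", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 2, replicate_a_sd = 0)
  terr <- generate_terrain(lay, seed = 2)
  sp <- session_spec(dap = 98, noise_sd = 0, outlier_fraction = 0,
                     occlusion_strength = 1, seed = 3)
  s <- generate_session_cloud(lay, asg, sp, terr, density = 500)
  ground <- s$cloud[s$cloud$kind == "terrain", ]
  state <- tls4d:::plot_canopy_state(asg, lay, 98)
  for (i in seq_len(nrow(state))) {
    r2 <- ((ground$x - state$cx[i]) / state$semi_a[i])^2 +
      ((ground$y - state$cy[i]) / state$semi_b[i])^2
    expect_equal(sum(r2 < 1), 0)
  }
})

test_that("unknown plot ids in the assignment are rejected", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 2)
  terr <- generate_terrain(lay, seed = 2)
  bad <- asg
  bad$plot_id[1] <- "P999"
  expect_error(
    generate_session_cloud(lay, bad, session_spec(dap = 40, seed = 1), terr,
                           density = 300),
    "unknown plot ids|cover every plot")
})

test_that("time series are reproducible, monotone in truth, and invertible", {
  lay <- tiny_layout()
  daps <- c(35, 56, 77, 98)
  a <- generate_timeseries(lay, assign_genotypes(lay, tiny_panel(), seed = 4),
                           daps = daps, seed = 4, density = 300)
  b <- generate_timeseries(lay, assign_genotypes(lay, tiny_panel(), seed = 4),
                           daps = daps, seed = 4, density = 300)
  for (i in seq_along(daps)) {
    expect_identical(a[[i]]$cloud$x, b[[i]]$cloud$x)
    expect_identical(a[[i]]$cloud$z, b[[i]]$cloud$z)
  }
  # per-plot true CH is non-decreasing in time (logistic monotonicity)
  truth <- series_truth(a)
  for (pid in unique(truth$plot_id)) {
    ch <- truth$ch[truth$plot_id == pid][order(daps)]
    expect_true(all(diff(ch) >= 0))
  }
  # single-session series: the emitted transform inverts exactly
  single <- generate_timeseries(lay, assign_genotypes(lay, tiny_panel(), seed = 4),
                                daps = 35, seed = 4, density = 300)
  rt <- compose_transforms(single[[1]]$truth$transform, single[[1]]$truth$inverse)
  expect_lt(max(abs(transform_matrix(rt) - diag(4))), 1e-9)
})

test_that("the inverse ground-truth transform recovers the unperturbed cloud", {
  lay <- tiny_layout()
  asg <- assign_genotypes(lay, tiny_panel(), seed = 6)
  terr <- generate_terrain(lay, seed = 6)
  set.seed(10)
  pert <- random_rigid_transform(0.5, 5)
  args <- list(dap = 62, noise_sd = 0.005, outlier_fraction = 0.002,
               occlusion_strength = 0.4, seed = 12)
  plain <- generate_session_cloud(lay, asg, do.call(session_spec, args), terr,
                                  density = 400)
  pset <- generate_session_cloud(lay, asg,
                                 do.call(session_spec, c(args, list(perturbation = pert))),
                                 terr, density = 400)
  recovered <- apply_transform(pset$cloud, pset$truth$inverse)
  expect_cloud_equal(recovered, plain$cloud, tol = 1e-9)
})

test_that("growth-record simulation matches its generating curve", {
  pars <- tibble::tibble(genotype = c("a", "b"), A = c(1.2, 2), k = 0.06,
                         Ti = c(50, 60))
  rec <- simulate_growth_records(pars, daps = c(40, 60, 80), n_reps = 3,
                                 noise_sd = 0, replicate_sd = 0, seed = 1)
  expect_equal(nrow(rec), 2 * 3 * 3)
  want <- sigmoid("logistic", rec$dap, pars$A[match(rec$genotype, pars$genotype)],
                  0.06, pars$Ti[match(rec$genotype, pars$genotype)])
  expect_equal(rec$value, want, tolerance = 1e-12)
  expect_identical(rec, simulate_growth_records(pars, daps = c(40, 60, 80),
                                                n_reps = 3, noise_sd = 0,
                                                replicate_sd = 0, seed = 1))
})
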