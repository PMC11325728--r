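#' Default cotton genotype panel
#'
#' Eleven upland/pima cotton genotypes with logistic growth parameters for
#' canopy height (`A_ch` m, `k_ch` 1/day, `Ti_ch` days after planting) and
#' canopy volume (`A_cv` m^3, `k_cv` 1/day, `Ti_cv` days). The values span
#' the range reported for replicated cotton breeding trials: asymptotic
#' heights between about 1.2 and 2.1 m with a common height growth rate of
#' 0.06 1/day, and asymptotic plot volumes between about 2.8 and 7.2 m^3
#' with a common volume growth rate of 0.106 1/day.
#'
#' @return A tibble with one row per genotype.
#' @export
cotton_genotypes <- function() {
  tibble::tribble(
    ~genotype,          ~A_ch, ~Ti_ch, ~A_cv, ~Ti_cv,
    "Tamcot Sphinx",     1.24,  53.3,   2.76,  64.4,
    "UA 48",             1.26,  51.2,   3.68,  64.8,
    "ST5020",            1.40,  49.1,   4.28,  65.3,
    "Acala Maxxa",       1.40,  53.2,   4.28,  64.0,
    "DP 1646",           1.48,  55.7,   4.77,  70.1,
    "T0246BC3MDN",       1.58,  53.3,   4.84,  66.1,
    "DG 3615",           1.59,  52.5,   6.67,  67.4,
    "DP 341",            1.62,  56.1,   6.45,  68.3,
    "DES 56",            1.81,  54.4,   6.49,  66.7,
    "MDN0101 (GH191)",   1.84,  57.7,   5.40,  62.6,
    "T0018MDN",          2.06,  59.3,   7.25,  67.0) |>
    dplyr::mutate(k_ch = 0.06, k_cv = 0.106, .after = "genotype")
}

#' Generate a smooth synthetic terrain surface
#'
#' Undulating bare-ground elevation as a sum of low-frequency random
#' harmonics over the field bounding box, normalized so the peak-to-peak
#' relief never exceeds `2 * relief_amplitude`. Deterministic per seed.
#'
#' @param layout A [field_layout()].
#' @param seed Integer seed.
#' @param relief_amplitude Half the maximum peak-to-peak relief (m), >= 0.
#' @param cell_size Grid resolution of the returned model (m).
#' @param margin Extra coverage beyond the field bounding box (m).
#' @return A [terrain_model()].
#' @export
generate_terrain <- function(layout, seed = 1, relief_amplitude = 0.2,
                             cell_size = 0.05, margin = 2) {
  stopifnot(relief_amplitude >= 0)
  ext <- layout_extent(layout, margin = margin)
  nx <- ceiling((ext["xmax"] - ext["xmin"]) / cell_size)
  ny <- ceiling((ext["ymax"] - ext["ymin"]) / cell_size)
  n_harm <- 6
  with_seed(derive_seed(seed, "terrain"), {
    amp <- runif(n_harm, 0.3, 1)
    wavelength <- runif(n_harm, 8, 40)          # low-frequency undulation only
    bearing <- runif(n_harm, 0, 2 * pi)
    phase <- runif(n_harm, 0, 2 * pi)
  })
  xs <- ext["xmin"] + (seq_len(nx) - 0.5) * cell_size
  ys <- ext["ymin"] + (seq_len(ny) - 0.5) * cell_size
  z <- matrix(0, nrow = ny, ncol = nx)
  if (relief_amplitude > 0) {
    for (h in seq_len(n_harm)) {
      kx <- 2 * pi / wavelength[h] * cos(bearing[h])
      ky <- 2 * pi / wavelength[h] * sin(bearing[h])
      z <- z + amp[h] * sin(outer(ys, xs, function(y, x) kx * x + ky * y) + phase[h])
    }
    z <- z * (relief_amplitude / sum(amp))
  }
  terrain_model(c(ext["xmin"], ext["ymin"]), cell_size, z)
}

#' Per-session simulation settings
#'
#' @param dap Days after planting, >= 0.
#' @param perturbation A `rigid_transform` applied to the finished session
#'   cloud (emulating an unknown scanner pose drift between sessions).
#' @param noise_sd Gaussian z-noise on terrain returns (m).
#' @param outlier_fraction Fraction of spurious uniform points in `[0, 1)`.
#' @param occlusion_strength In `[0, 1]`: scales the probability that a
#'   terrain return under the canopy is lost; 1 removes every under-canopy
#'   terrain point.
#' @param seed Integer seed for this session's sampling.
#' @export
session_spec <- function(dap, perturbation = rigid_transform(),
                         noise_sd = 0.005, outlier_fraction = 0.002,
                         occlusion_strength = 0, seed = 1) {
  stopifnot(dap >= 0, noise_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            occlusion_strength >= 0, occlusion_strength <= 1)
  structure(list(dap = dap, perturbation = perturbation, noise_sd = noise_sd,
                 outlier_fraction = outlier_fraction,
                 occlusion_strength = occlusion_strength, seed = seed),
            class = "session_spec")
}

logistic_curve <- function(t, A, k, Ti) A * stats::plogis(k * (t - Ti))

#' Assign genotypes to plots in a randomized complete block design
#'
#' Each field row is one replicate block containing every genotype once, in
#' a per-block random order (deterministic per seed). Requires
#' `plots_per_row == nrow(genotype_table)`.
#'
#' @param layout A [field_layout()].
#' @param genotype_table Tibble as returned by [cotton_genotypes()].
#' @param seed Integer seed.
#' @param replicate_a_sd Between-replicate standard deviation of the height
#'   asymptote (m): each block draws one additive deviation applied to
#'   `A_ch`, with `A_cv` scaled by the same relative amount. Gives the
#'   replicate random effect that the growth model estimates.
#' @return Per-plot assignment tibble (one row per plot) with the genotype's
#'   growth parameters attached.
#' @export
assign_genotypes <- function(layout, genotype_table = cotton_genotypes(),
                             seed = 1, replicate_a_sd = 0.03) {
  stopifnot(layout$plots_per_row == nrow(genotype_table))
  centers <- layout_centers(layout)
  with_seed(derive_seed(seed, "assign"), {
    orders <- lapply(seq_len(layout$n_rows), function(r) sample.int(nrow(genotype_table)))
    u <- rnorm(layout$n_rows, 0, replicate_a_sd)
  })
  rows <- purrr::map(seq_len(layout$n_rows), function(r) {
    g <- genotype_table[orders[[r]], ]
    rel <- u[r] / g$A_ch
    tibble::tibble(
      plot_id = plot_id_for(r, seq_len(layout$plots_per_row)),
      row = r, col = seq_len(layout$plots_per_row),
      genotype = g$genotype, replicate = sprintf("R%d", r),
      A_ch = g$A_ch + u[r], k_ch = g$k_ch, Ti_ch = g$Ti_ch,
      A_cv = g$A_cv * (1 + rel), k_cv = g$k_cv, Ti_cv = g$Ti_cv)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out, centers, by = c("row", "col"))
}

# True per-plot canopy state at a given DAP: height, footprint semi-axes,
# projected area and volume. The footprint follows its own logistic (tied to
# the CV target) so that CA * CH reproduces the CV curve until the footprint
# saturates at the plot rectangle.
plot_canopy_state <- function(assignment, layout, dap) {
  ch <- logistic_curve(dap, assignment$A_ch, assignment$k_ch, assignment$Ti_ch)
  cv_target <- logistic_curve(dap, assignment$A_cv, assignment$k_cv, assignment$Ti_cv)
  amax <- layout$plot_length / 2
  bmax <- layout$row_spacing / 2
  s <- sqrt(pmin(1, cv_target / pmax(ch, 1e-9) / (pi * amax * bmax)))
  a <- s * amax
  b <- s * bmax
  ca <- pi * a * b
  dplyr::mutate(assignment, dap = dap, ch = ch, semi_a = a, semi_b = b,
                ca = ca, cv = ca * ch)
}

#' Generate one session's field point cloud with ground truth
#'
#' Builds (a) terrain returns on a jittered grid with Gaussian z-noise,
#' thinned under canopies according to `occlusion_strength`; (b) per-plot
#' canopy points sampled uniformly inside a half-ellipsoid whose height
#' follows the plot's logistic growth curve and whose footprint grows toward
#' the plot rectangle, plus one apex point at the plant terminal so the true
#' maximum height is attained; and (c) uniform outlier noise. The finished
#' cloud is rigidly perturbed by `session$perturbation`.
#'
#' @param layout A [field_layout()].
#' @param assignment Per-plot genotype assignment from [assign_genotypes()].
#' @param session A [session_spec()].
#' @param terrain A [terrain_model()] from [generate_terrain()].
#' @param density Canopy point density (points/m^3).
#' @param ground_spacing Terrain return spacing (m).
#' @return A list with `cloud` (point cloud; `kind` attribute column with
#'   values terrain/canopy/outlier and `plot_id` for canopy points) and
#'   `truth` (a `session_truth`: the applied perturbation, its inverse, and
#'   the per-plot true CH/CA/CV/centroids).
#' @export
generate_session_cloud <- function(layout, assignment, session, terrain,
                                   density = 5000, ground_spacing = 0.10) {
  stopifnot(inherits(session, "session_spec"))
  expected <- plot_id_for(rep(seq_len(layout$n_rows), each = layout$plots_per_row),
                          rep(seq_len(layout$plots_per_row), layout$n_rows))
  if (!setequal(assignment$plot_id, expected)) {
    bad <- setdiff(assignment$plot_id, expected)
    if (length(bad) > 0) stop("unknown plot ids in assignment: ",
                              paste(head(bad, 3), collapse = ", "))
    stop("plot assignment must cover every plot in the layout")
  }
  state <- plot_canopy_state(assignment, layout, session$dap)
  ext <- layout_extent(layout, margin = 1)
  with_seed(derive_seed(session$seed, "session", session$dap), {
    # --- terrain returns -------------------------------------------------
    xs <- seq(ext["xmin"], ext["xmax"], by = ground_spacing)
    ys <- seq(ext["ymin"], ext["ymax"], by = ground_spacing)
    gx <- rep(xs, times = length(ys)) + runif(length(xs) * length(ys), -0.5, 0.5) * ground_spacing
    gy <- rep(ys, each = length(xs)) + runif(length(xs) * length(ys), -0.5, 0.5) * ground_spacing
    gz <- terrain_height(terrain, gx, gy) +
      (if (session$noise_sd > 0) rnorm(length(gx), 0, session$noise_sd) else 0)
    # occlusion: thin under-canopy returns with probability growing with the
    # overlying canopy thickness, saturating at full removal when
    # occlusion_strength = 1
    drop <- rep(FALSE, length(gx))
    if (session$occlusion_strength > 0) {
      u <- runif(length(gx))
      for (i in seq_len(nrow(state))) {
        if (state$semi_a[i] <= 0) next
        dx <- gx - state$cx[i]; dy <- gy - state$cy[i]
        inside <- abs(dx) < state$semi_a[i] & abs(dy) < state$semi_b[i]
        if (!any(inside)) next
        r2 <- (dx[inside] / state$semi_a[i])^2 + (dy[inside] / state$semi_b[i])^2
        under <- r2 < 1
        thick <- sqrt(pmax(0, 1 - r2[under]))
        p <- pmin(1, session$occlusion_strength * (1 + thick))
        sel <- which(inside)[under]
        drop[sel] <- drop[sel] | (u[sel] < p)
      }
    }
    ground <- tibble::tibble(x = gx[!drop], y = gy[!drop], z = gz[!drop],
                             kind = "terrain", plot_id = NA_character_)

    # --- canopy points ---------------------------------------------------
    canopy <- purrr::map(seq_len(nrow(state)), function(i) {
      a <- state$semi_a[i]; b <- state$semi_b[i]; h <- state$ch[i]
      vol <- 2 / 3 * pi * a * b * h
      n <- round(density * vol)
      pts <- if (n > 0) sample_half_ellipsoid(n) else matrix(0, 0, 3)
      px <- state$cx[i] + pts[, 1] * a
      py <- state$cy[i] + pts[, 2] * b
      # apex point: the plant terminal, guaranteeing max height = CH
      px <- c(px, state$cx[i]); py <- c(py, state$cy[i])
      ph <- c(pts[, 3] * h, h)
      tibble::tibble(x = px, y = py,
                     z = terrain_height(terrain, px, py) + ph,
                     kind = "canopy", plot_id = state$plot_id[i])
    })
    cloud <- dplyr::bind_rows(ground, canopy)

    # --- outliers --------------------------------------------------------
    n_out <- round(session$outlier_fraction * nrow(cloud))
    if (n_out > 0) {
      zr <- range(cloud$z)
      cloud <- dplyr::bind_rows(cloud, tibble::tibble(
        x = runif(n_out, ext["xmin"], ext["xmax"]),
        y = runif(n_out, ext["ymin"], ext["ymax"]),
        z = runif(n_out, zr[1] - 0.5, zr[2] + 1.5),
        kind = "outlier", plot_id = NA_character_))
    }
  })
  cloud <- as_point_cloud(cloud)
  n_canopy <- dplyr::count(dplyr::filter(cloud, .data$kind == "canopy"),
                           .data$plot_id, name = "n_canopy_points")
  cloud <- apply_transform(cloud, session$perturbation)
  truth <- structure(list(
    dap = session$dap,
    occlusion_strength = session$occlusion_strength,
    transform = session$perturbation,
    inverse = invert_transform(session$perturbation),
    plots = dplyr::left_join(
      dplyr::select(state, "plot_id", "genotype", "replicate", "dap",
                    "ch", "ca", "cv", centroid_x = "cx", centroid_y = "cy"),
      n_canopy, by = "plot_id")),
    class = "session_truth")
  list(cloud = cloud, truth = truth)
}

# Uniform samples in the unit upper half-ball (z in [0, 1]), by rejection.
sample_half_ellipsoid <- function(n) {
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / 0.5) + 8
    cand <- cbind(runif(m, -1, 1), runif(m, -1, 1), runif(m, 0, 1))
    keep <- rowSums(cand^2) <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a ground-truthed multi-session time series
#'
#' One session per entry of `daps` (strictly increasing), sharing a single
#' terrain surface and genotype assignment. The first session gets an
#' identity perturbation and defines the global frame (mirroring the use of
#' the first survey as the registration reference); later sessions receive
#' independent random rigid perturbations within `max_translation` /
#' `max_angle_deg`. Occlusion strength increases linearly across sessions
#' between `occlusion_range[1]` and `occlusion_range[2]`, reproducing the
#' progressive loss of under-canopy terrain returns as the canopy closes.
#'
#' @param layout A [field_layout()].
#' @param assignment From [assign_genotypes()]; built automatically when
#'   omitted.
#' @param daps Session times (days after planting), strictly increasing.
#' @param seed Integer seed controlling every random draw.
#' @param max_translation,max_angle_deg Per-axis perturbation bounds.
#' @param occlusion_range Length-2 occlusion schedule endpoints.
#' @param occlusion_strengths Optional explicit per-session occlusion
#'   strengths (overrides the linear schedule).
#' @param noise_sd,outlier_fraction Passed to each [session_spec()].
#' @param density,ground_spacing Passed to [generate_session_cloud()].
#' @return A `field_series` list of `list(cloud, truth)` with the layout,
#'   terrain and assignment attached as attributes.
#' @export
generate_timeseries <- function(layout = field_layout(),
                                assignment = NULL,
                                daps = c(35, 42, 49, 56, 62, 70, 77, 84, 98),
                                seed = 1,
                                max_translation = 0.5, max_angle_deg = 5,
                                occlusion_range = c(0.05, 0.95),
                                occlusion_strengths = NULL,
                                noise_sd = 0.005, outlier_fraction = 0.002,
                                density = 5000, ground_spacing = 0.10) {
  stopifnot(length(daps) >= 1, !is.unsorted(daps, strictly = TRUE))
  if (is.null(assignment)) assignment <- assign_genotypes(layout, seed = seed)
  terrain <- generate_terrain(layout, seed = seed)
  occl <- occlusion_strengths %||%
    (if (length(daps) == 1) occlusion_range[1] else
       seq(occlusion_range[1], occlusion_range[2], length.out = length(daps)))
  stopifnot(length(occl) == length(daps))
  sessions <- purrr::map(seq_along(daps), function(i) {
    pert <- if (i == 1) rigid_transform() else
      with_seed(derive_seed(seed, "perturb", i),
                random_rigid_transform(max_translation, max_angle_deg))
    spec <- session_spec(dap = daps[i], perturbation = pert,
                         noise_sd = noise_sd,
                         outlier_fraction = outlier_fraction,
                         occlusion_strength = occl[i],
                         seed = derive_seed(seed, "cloud", i))
    generate_session_cloud(layout, assignment, spec, terrain,
                           density = density, ground_spacing = ground_spacing)
  })
  structure(sessions, class = "field_series", layout = layout,
            terrain = terrain, assignment = assignment, daps = daps)
}

#' True plot trait table of a simulated series
#'
#' @param series A `field_series` from [generate_timeseries()].
#' @return Tibble of per plot x session ground-truth CH/CA/CV.
#' @export
series_truth <- function(series) {
  dplyr::bind_rows(purrr::map(series, function(s) s$truth$plots))
}

#' Simulate plot-level trait records from logistic growth
#'
#' Direct trait-table simulator for exercising the growth-modeling stage
#' without running the point-cloud pipeline: one record per genotype x
#' replicate x time with value
#' `(A_g + u_r) / (1 + exp(-k (t - Ti_g))) + e`,
#' `u_r ~ N(0, replicate_sd^2)` a replicate (block) intercept on the
#' asymptote and `e ~ N(0, noise_sd^2)` residual noise.
#'
#' @param params Tibble with `genotype`, `A`, `k`, `Ti` columns.
#' @param daps Observation times (days after planting).
#' @param n_reps Number of replicate blocks.
#' @param noise_sd Residual standard deviation (trait units).
#' @param replicate_sd Replicate-intercept standard deviation on `A`.
#' @param seed Integer seed.
#' @return Tibble with `plot_id`, `genotype`, `replicate`, `dap`, `value`.
#' @export
simulate_growth_records <- function(params, daps = c(35, 42, 49, 56, 62, 70, 77, 84, 98),
                                    n_reps = 8, noise_sd = 0.05,
                                    replicate_sd = 0, seed = 1) {
  stopifnot(all(c("genotype", "A", "k", "Ti") %in% names(params)))
  with_seed(derive_seed(seed, "records"), {
    u <- rnorm(n_reps, 0, replicate_sd)
    grid <- tidyr::expand_grid(g = seq_len(nrow(params)), rep = seq_len(n_reps),
                               dap = daps)
    mu <- logistic_curve(grid$dap, params$A[grid$g] + u[grid$rep],
                         params$k[grid$g], params$Ti[grid$g])
    tibble::tibble(
      plot_id = sprintf("P%d%02d", grid$rep, grid$g),
      genotype = params$genotype[grid$g],
      replicate = sprintf("R%d", grid$rep),
      dap = grid$dap,
      value = mu + rnorm(nrow(grid), 0, noise_sd))
  })
}
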