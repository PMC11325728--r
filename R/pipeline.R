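#' Register a multi-session series against its first session
#'
#' Runs the per-session conditioning ([preprocess_session()]) and then the
#' two-phase pairwise registration of every later session onto the first
#' (the reference), followed by the global height renormalization against
#' the reference terrain.
#'
#' @param series A `field_series` (or any list of `list(cloud = ...)`).
#' @param config A [pipeline_config()].
#' @param inits Optional list of per-session initial transforms seeding the
#'   terrain ICP (the role the scanner's GPS/inclinometer pose plays in the
#'   field workflow); see [coarse_pose_guesses()]. Identity when omitted.
#' @return List with `registered` (renormalized clouds, trait-ready),
#'   `registered_raw` (registered, unnormalized), `preprocessed`
#'   (per-session conditioning output), `transforms`, `phases`,
#'   `icp_rms`, and `ref_terrain`.
#' @export
register_series <- function(series, config = pipeline_config(), inits = NULL) {
  pp <- purrr::map(series, function(s)
    preprocess_session(s$cloud, config$preprocess))
  ref <- pp[[1]]
  regs <- purrr::map(seq_along(pp), function(i) {
    if (i == 1) {
      return(list(transform = rigid_transform(), phase = "reference",
                  icp = list(rms = 0), n_pairs = NA_integer_))
    }
    params <- config$registration
    if (!is.null(inits)) params$init <- inits[[i]]
    register_pair(pp[[i]]$raw, ref$raw, pp[[i]]$terrain, ref$terrain, params)
  })
  registered_raw <- purrr::map(seq_along(pp), function(i)
    apply_transform(pp[[i]]$raw, regs[[i]]$transform))
  registered <- suppressWarnings(global_renormalize(registered_raw, ref$terrain))
  list(registered = registered, registered_raw = registered_raw,
       preprocessed = pp,
       transforms = purrr::map(regs, "transform"),
       phases = vapply(regs, function(r) r$phase, character(1)),
       icp_rms = vapply(regs, function(r) r$icp$rms, numeric(1)),
       details = regs, ref_terrain = ref$terrain)
}

#' Evaluate a registered series against simulator ground truth
#'
#' For each non-reference session, compares the estimated placement of the
#' session's (preprocessed) cloud with its ground-truth placement — the
#' same point set under the true inverse perturbation — via nearest-neighbor
#' residuals and the directed Hausdorff distance, for both the phase-1-only
#' and the final transform.
#'
#' @param series The `field_series` the registration was run on.
#' @param reg Output of [register_series()].
#' @param max_points Decimation cap per cloud for the comparison.
#' @return Tibble: one row per session with `dap`, `occlusion`, `phase`,
#'   `hausdorff_phase1`, `hausdorff_final`, `rms_final` (meters).
#' @export
evaluate_series <- function(series, reg, max_points = 40000) {
  rows <- purrr::map(seq_along(series), function(i) {
    if (i == 1) return(NULL)
    raw <- decimate_cloud(reg$preprocessed[[i]]$raw, max_points)
    truth <- apply_transform(raw, series[[i]]$truth$inverse)
    final <- apply_transform(raw, reg$transforms[[i]])
    phase1 <- apply_transform(raw, reg$details[[i]]$icp$transform)
    rep_final <- registration_report(final, truth, phase = reg$phases[i])
    tibble::tibble(
      session = i, dap = series[[i]]$truth$dap,
      occlusion = series[[i]]$truth$occlusion_strength,
      phase = reg$phases[i],
      hausdorff_phase1 = hausdorff_directed(phase1, truth),
      hausdorff_final = rep_final$hausdorff,
      rms_final = rep_final$rms)
  })
  dplyr::bind_rows(rows)
}

#' Coarse pose guesses for a simulated series
#'
#' Builds the per-session initial transforms that seed the terrain ICP, as
#' the noisy inverse of each session's true perturbation: the simulator's
#' stand-in for the coarse scanner pose a GPS receiver and inclinometer
#' provide in the field (position within a fraction of a meter, attitude
#' within about a degree). Deterministic per seed.
#'
#' @param series A `field_series`.
#' @param max_translation_error Per-axis position-guess error bound (m).
#' @param max_angle_error_deg Per-axis attitude-guess error bound (deg).
#' @param seed Integer seed.
#' @return List of `rigid_transform`s, one per session (identity for the
#'   reference session).
#' @export
coarse_pose_guesses <- function(series, max_translation_error = 0.3,
                                max_angle_error_deg = 1, seed = 1) {
  purrr::map(seq_along(series), function(i) {
    if (i == 1) return(rigid_transform())
    err <- with_seed(derive_seed(seed, "pose-guess", i),
                     random_rigid_transform(max_translation_error,
                                            max_angle_error_deg))
    compose_transforms(err, series[[i]]$truth$inverse)
  })
}

decimate_cloud <- function(cloud, n) {
  if (nrow(cloud) <= n) return(cloud)
  cloud[unique(round(seq(1, nrow(cloud), length.out = n))), ]
}

#' Extract the trait table of a registered series
#'
#' @param registered List of registered, globally renormalized clouds.
#' @param grid A `plot_grid` with genotype metadata.
#' @param daps Session times (days after planting), one per cloud.
#' @param config A [pipeline_config()].
#' @return Combined per plot x session trait tibble.
#' @export
series_traits <- function(registered, grid, daps,
                          config = pipeline_config()) {
  stopifnot(length(registered) == length(daps))
  dplyr::bind_rows(purrr::map(seq_along(registered), function(i)
    extract_traits(registered[[i]], grid, dap = daps[i],
                   veg_threshold = config$traits$veg_threshold,
                   pixel = config$traits$ca_pixel)))
}

#' Run the full demonstration pipeline on simulated data
#'
#' Simulates a ground-truthed multi-session field series, runs
#' preprocessing, two-phase registration, evaluation against the known
#' truth, trait extraction and growth modeling, and writes all artifacts
#' (plot grid, trait table, registration table, growth tables, JSON
#' report) to `out_dir`. Fully deterministic per seed.
#'
#' The default demo scale is a 4-row x 6-plot field over 5 sessions at
#' moderate point density, which exercises every stage in a few minutes on
#' one core.
#'
#' @param seed Integer seed for every random draw.
#' @param out_dir Output directory (created if missing).
#' @param config Optional [pipeline_config()] override; the demo scale is
#'   used when omitted.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with the series, registration, evaluation,
#'   trait table and growth fits.
#' @export
demo_pipeline <- function(seed = 1, out_dir = tempfile("tls4d-demo-"),
                          config = NULL, quiet = FALSE) {
  if (is.null(config)) config <- demo_config(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  sim <- config$simulate
  layout <- layout_from_config(config)
  panel <- cotton_genotypes()
  if (layout$plots_per_row < nrow(panel)) {
    panel <- panel[round(seq(1, nrow(panel), length.out = layout$plots_per_row)), ]
  }
  assignment <- assign_genotypes(layout, panel, seed = config$seed,
                                 replicate_a_sd = sim$replicate_a_sd)

  say("simulating ", length(sim$daps), " sessions ...")
  series <- generate_timeseries(
    layout, assignment, daps = sim$daps, seed = config$seed,
    max_translation = sim$max_translation, max_angle_deg = sim$max_angle_deg,
    occlusion_range = sim$occlusion_range, noise_sd = sim$noise_sd,
    outlier_fraction = sim$outlier_fraction, density = sim$density,
    ground_spacing = sim$ground_spacing)
  grid <- layout_plot_grid(layout, genotypes = assignment)
  write_plot_grid(grid, file.path(out_dir, "plots.geojson"))

  say("registering ...")
  inits <- coarse_pose_guesses(series, seed = config$seed)
  reg <- register_series(series, config, inits = inits)
  ev <- evaluate_series(series, reg)
  for (i in seq_along(series)) {
    write_transform(reg$transforms[[i]],
                    file.path(out_dir, sprintf("transform_s%02d.txt", i)))
  }
  write.csv(ev, file.path(out_dir, "registration_eval.csv"), row.names = FALSE)

  say("extracting traits ...")
  traits <- series_traits(reg$registered, grid, attr(series, "daps"), config)
  write.csv(traits, file.path(out_dir, "traits.csv"), row.names = FALSE)
  truth <- series_truth(series)

  say("fitting growth curves ...")
  fits <- purrr::map(config$growth$models, function(m)
    fit_growth(traits, trait = "ch_max", model = m,
               restarts = config$growth$restarts))
  names(fits) <- config$growth$models
  comparison <- compare_models(fits)
  write.csv(comparison, file.path(out_dir, "model_comparison_ch.csv"),
            row.names = FALSE)
  best <- fits[[comparison$model[1]]]
  partab <- genotype_parameter_table(best, config$growth$correction)
  write.csv(partab, file.path(out_dir, "growth_parameters_ch.csv"),
            row.names = FALSE)

  acc <- dplyr::inner_join(
    dplyr::select(traits, "plot_id", "dap", "ch_max"),
    dplyr::select(truth, "plot_id", "dap", ch_true = "ch"),
    by = c("plot_id", "dap"))
  acc <- acc[!is.na(acc$ch_max) & acc$ch_true > 0.05, ]
  ch_metrics <- regression_metrics(acc$ch_true, acc$ch_max)

  report <- list(
    seed = config$seed,
    n_sessions = length(series),
    daps = attr(series, "daps"),
    registration = list(
      phases = reg$phases,
      mean_hausdorff_phase1_cm = mean(ev$hausdorff_phase1) * 100,
      mean_hausdorff_final_cm = mean(ev$hausdorff_final) * 100,
      per_session = ev),
    traits = list(n_records = nrow(traits), ch_vs_truth = ch_metrics),
    growth = list(best_model = comparison$model[1],
                  comparison = comparison,
                  parameters = partab))
  jsonlite::write_json(report, file.path(out_dir, "demo_report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  say("done: ", out_dir)
  invisible(list(series = series, registration = reg, evaluation = ev,
                 traits = traits, truth = truth, fits = fits,
                 comparison = comparison, parameter_table = partab,
                 report = report, out_dir = out_dir))
}

#' Demo-scale configuration
#'
#' @param seed Integer seed.
#' @export
demo_config <- function(seed = 1) {
  pipeline_config(
    seed = seed,
    simulate = list(
      n_rows = 4, plots_per_row = 6,
      daps = c(35, 49, 62, 77, 98),
      occlusion_range = c(0.05, 0.6),
      density = 700, ground_spacing = 0.15))
}
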