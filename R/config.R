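#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list, with defaults
#' matching the standard field protocol: SOR with 20 neighbors and a 2.5 sd
#' band, 5 mm subsampling, 10 cm DTM cells, a 0.9 m centroid-matching gate
#' (half the 1.83 m row spacing), a 5 cm vegetation threshold and a 1 cm
#' canopy-area pixel. Override entries via `...` using nested lists, e.g.
#' `pipeline_config(preprocess = list(sor_neighbors = 10))`.
#'
#' @param ... Named overrides merged (recursively) over the defaults;
#'   unknown keys are rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    simulate = list(
      n_rows = 8, plots_per_row = 11,
      plot_length = 3.05, row_spacing = 1.83, alley_width = 1.52,
      row_axis_bearing = 0,
      daps = c(35, 42, 49, 56, 62, 70, 77, 84, 98),
      relief_amplitude = 0.2,
      occlusion_range = c(0.05, 0.95),
      noise_sd = 0.005, outlier_fraction = 0.002,
      max_translation = 0.5, max_angle_deg = 5,
      replicate_a_sd = 0.03,
      density = 5000, ground_spacing = 0.10),
    preprocess = list(
      sor_neighbors = 20, sor_std_ratio = 2.5,
      subsample_distance = 0.005, dtm_cell_size = 0.10),
    registration = list(
      icp_max_iter = 100, icp_tol = 1e-6, icp_max_corr_dist = 0.5,
      bev_resolution = 0.05, bev_veg_threshold = 0.05,
      row_axis_bearing = 0, knn_gate = 0.9, init = NULL),
    traits = list(veg_threshold = 0.05, ca_pixel = NULL, ch_method = "max"),
    growth = list(models = c("logistic", "gompertz", "richards3p"),
                  correction = "bonferroni", restarts = 3))
  out <- merge_config(defaults, list(...), path = "")
  class(out) <- c("pipeline_config", "list")
  out
}

merge_config <- function(base, override, path) {
  if (length(override) == 0) return(base)
  bad <- setdiff(names(override), names(base))
  if (length(bad) > 0) {
    stop("unknown config key", if (length(bad) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  }
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, ".", nm))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a pipeline configuration as YAML
#'
#' The file holds only overrides or a full dump; on reading, entries are
#' validated against the known schema (unknown keys are an error) and
#' merged over the defaults, so a written config round-trips losslessly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

layout_from_config <- function(config) {
  s <- config$simulate
  field_layout(s$n_rows, s$plots_per_row, s$plot_length, s$row_spacing,
               s$alley_width, s$row_axis_bearing)
}
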