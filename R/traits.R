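#' Assign points to plots
#'
#' Each point is assigned to the plot-grid rectangle containing its XY
#' (half-open on the upper/right edges so boundary points belong to exactly
#' one plot), or to none.
#'
#' @param cloud A point cloud registered into the grid's frame.
#' @param grid A `plot_grid`.
#' @return `assign_plots` returns the cloud with a `plot_id` column (`NA`
#'   outside all plots); `segment_plots` returns a named list of per-plot
#'   clouds.
#' @export
assign_plots <- function(cloud, grid) {
  plot_id <- rep(NA_character_, nrow(cloud))
  for (i in seq_len(nrow(grid))) {
    idx <- points_in_plot(grid, i, cloud$x, cloud$y)
    plot_id[idx] <- grid$plot_id[i]
  }
  cloud$plot_id <- plot_id
  cloud
}

#' @rdname assign_plots
#' @export
segment_plots <- function(cloud, grid) {
  cloud$plot_id <- NULL
  assigned <- assign_plots(cloud, grid)
  assigned <- assigned[!is.na(assigned$plot_id), ]
  out <- split(dplyr::select(assigned, -"plot_id"), assigned$plot_id)
  lapply(out, as_point_cloud)
}

#' Plot-level canopy height
#'
#' The chosen percentile (95th or 99th, linear interpolation) or the
#' maximum of the normalized heights of all points in the plot.
#'
#' @param plot_cloud Height-normalized point cloud of one plot.
#' @param method One of `"max"`, `"p95"`, `"p99"`.
#' @return Height in meters; `NA` for an empty plot.
#' @export
canopy_height <- function(plot_cloud, method = c("max", "p95", "p99")) {
  method <- match.arg(method)
  if (is.null(plot_cloud) || nrow(plot_cloud) == 0) return(NA_real_)
  switch(method,
         max = max(plot_cloud$z),
         p95 = quantile(plot_cloud$z, 0.95, names = FALSE),
         p99 = quantile(plot_cloud$z, 0.99, names = FALSE))
}

#' Projected canopy area
#'
#' Vegetation points (`z > veg_threshold`) are projected onto XY and
#' rasterized to a binary mask at `pixel` resolution inside the plot
#' rectangle; the area is the occupied-pixel count times the pixel area
#' (equivalently `numPixels * shapeSize_m / shapeSize_px`). Invariant to
#' point density once every canopy pixel holds at least one point.
#'
#' A fixed 1 cm pixel is appropriate for survey-grade clouds (5 mm point
#' spacing). For sparser clouds the mask must not be finer than the
#' projected point spacing, so when `pixel` is omitted it is chosen
#' adaptively as twice the mean projected spacing of the plot's vegetation
#' points, floored at 1 cm; `fill_holes` additionally closes single-pixel
#' gaps in the mask (a physical canopy projects to a filled region).
#'
#' @param plot_cloud Height-normalized point cloud of one plot.
#' @param plot_polygon One-row slice of a `plot_grid` (the plot rectangle).
#' @param veg_threshold Vegetation height cut (m), default 5 cm.
#' @param pixel Mask pixel size (m), or `NULL` for the adaptive choice.
#' @param fill_holes Close single-pixel holes before counting.
#' @return Area in m^2 (0 when no vegetation).
#' @export
canopy_area <- function(plot_cloud, plot_polygon, veg_threshold = 0.05,
                        pixel = NULL, fill_holes = TRUE) {
  if (is.null(plot_cloud) || nrow(plot_cloud) == 0) return(0)
  veg <- plot_cloud[plot_cloud$z > veg_threshold, ]
  if (nrow(veg) == 0) return(0)
  # rasterize in the plot's local frame so the mask aligns with the rectangle
  b <- plot_polygon$bearing_deg[1] * pi / 180
  dx <- veg$x - plot_polygon$cx[1]
  dy <- veg$y - plot_polygon$cy[1]
  lx <- cos(b) * dx + sin(b) * dy + plot_polygon$length[1] / 2
  ly <- -sin(b) * dx + cos(b) * dy + plot_polygon$width[1] / 2
  inside <- lx >= 0 & lx < plot_polygon$length[1] & ly >= 0 & ly < plot_polygon$width[1]
  if (!any(inside)) return(0)
  if (is.null(pixel)) {
    # rough footprint from a coarse (10 cm) pass -> projected density ->
    # pixel ~ 2.2 / sqrt(density), clamped to [1, 8] cm
    rough <- length(unique(floor(lx[inside] / 0.1) +
                             1e6 * floor(ly[inside] / 0.1))) * 0.01
    dens <- sum(inside) / max(rough, 0.01)
    pixel <- min(max(2.2 / sqrt(dens), 0.01), 0.08)
  }
  nx <- ceiling(plot_polygon$length[1] / pixel)
  ny <- ceiling(plot_polygon$width[1] / pixel)
  px <- floor(lx[inside] / pixel) + 1
  py <- floor(ly[inside] / pixel) + 1
  if (fill_holes) {
    m <- matrix(0, ny, nx)
    m[cbind(py, px)] <- 1
    m <- as.matrix(EBImage::closing(m, EBImage::makeBrush(3, shape = "box")))
    n_pix <- sum(m > 0)
  } else {
    n_pix <- length(unique(px + (nx + 1) * py))
  }
  n_pix * pixel^2
}

#' Canopy volume from projected area and height
#'
#' `CV = CA * CH`.
#'
#' @param ca Projected canopy area (m^2), >= 0.
#' @param ch Canopy height (m), >= 0.
#' @export
canopy_volume <- function(ca, ch) {
  stopifnot(all(ca >= 0, na.rm = TRUE), all(ch >= 0, na.rm = TRUE))
  ca * ch
}

#' Fraction of intercepted photosynthetically active radiation
#'
#' `IPARf = (PAR_above - PAR_below) / PAR_above`.
#'
#' @param par_above Above-canopy irradiance, > 0.
#' @param par_below Below-canopy PAR, in `[0, par_above]`.
#' @export
ipar_fraction <- function(par_above, par_below) {
  if (any(par_above <= 0)) stop("par_above must be > 0")
  if (any(par_below < 0) || any(par_below > par_above)) {
    stop("par_below must lie in [0, par_above]")
  }
  (par_above - par_below) / par_above
}

#' Extract the plot trait table from one session
#'
#' Segments the cloud with the plot grid and computes CH (p95/p99/max), CA
#' and CV (from CHmax) per plot. Empty plots are recorded with missing
#' trait values, not zeros.
#'
#' @param cloud Height-normalized, registered session cloud.
#' @param grid A `plot_grid` carrying genotype/replicate metadata.
#' @param dap Days after planting of the session.
#' @param veg_threshold,pixel Passed to [canopy_area()].
#' @return Tibble: `plot_id`, `genotype`, `replicate`, `dap`, `ch_p95`,
#'   `ch_p99`, `ch_max`, `ca`, `cv`, `n_points`.
#' @export
extract_traits <- function(cloud, grid, dap = NA_real_, veg_threshold = 0.05,
                           pixel = NULL) {
  plots <- segment_plots(cloud, grid)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    pc <- plots[[grid$plot_id[i]]]
    ch_max <- canopy_height(pc, "max")
    ca <- canopy_area(pc, grid[i, ], veg_threshold = veg_threshold, pixel = pixel)
    tibble::tibble(
      plot_id = grid$plot_id[i],
      genotype = grid$genotype[i],
      replicate = grid$replicate[i],
      dap = dap,
      ch_p95 = canopy_height(pc, "p95"),
      ch_p99 = canopy_height(pc, "p99"),
      ch_max = ch_max,
      ca = ca,
      cv = if (is.na(ch_max)) NA_real_ else canopy_volume(ca, ch_max),
      n_points = if (is.null(pc)) 0L else nrow(pc))
  })
  dplyr::bind_rows(rows)
}

#' Regression performance metrics
#'
#' Coefficient of determination `R^2 = 1 - SS_res / SS_tot`, root mean
#' squared error, and mean absolute percentage error (in percent).
#'
#' @param y Observed values.
#' @param y_hat Predicted values (same length).
#' @return A one-row tibble with `r2`, `rmse`, `mape`.
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  if (any(y == 0)) stop("MAPE undefined: observed values contain zeros")
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble::tibble(
    r2 = 1 - ss_res / ss_tot,
    rmse = sqrt(mean((y - y_hat)^2)),
    mape = mean(abs((y - y_hat) / y)) * 100)
}

#' Standard error of regression
#'
#' `SER = sqrt( sum((y - y_hat)^2) / (n - (p + 1)) )` where `p` is the
#' number of model coefficients excluding the intercept.
#'
#' @param y,y_hat Observed and predicted values.
#' @param p Number of model coefficients (not counting the intercept).
#' @export
ser <- function(y, y_hat, p) {
  n <- length(y)
  stopifnot(length(y_hat) == n)
  if (n <= p + 1) stop("SER needs n > p + 1")
  sqrt(sum((y - y_hat)^2) / (n - (p + 1)))
}

#' Fit the light-interception saturation curve
#'
#' Nonlinear least-squares fit of the Beer-Lambert-type saturation
#' `IPARf = a (1 - exp(-b CV))` with asymptote `a` in (0, 1] and rate `b`
#' > 0 (per m^3), the expected relationship between canopy volume and the
#' fraction of intercepted radiation. Goodness of fit is summarized by the
#' standard error of regression with `p = 2` coefficients.
#'
#' @param cv Canopy volumes (m^3), >= 0.
#' @param ipar Intercepted-PAR fractions in `[0, 1]`.
#' @return A `light_fit` object with `asymptote`, `rate`, `ser`, `n`,
#'   fitted values and a `degenerate` flag (constant-response input).
#' @export
fit_light_interception <- function(cv, ipar) {
  stopifnot(length(cv) == length(ipar))
  ok <- complete.cases(cv, ipar)
  cv <- cv[ok]; ipar <- ipar[ok]
  if (length(cv) < 5) stop("need at least 5 observations")
  # nominal range is [0, 1]; small excursions from sensor noise are tolerated
  if (any(cv < 0) || any(ipar < -0.25) || any(ipar > 1.25)) {
    stop("cv must be >= 0 and ipar within [0, 1] (up to noise)")
  }
  if (sd(ipar) < 1e-12) {
    out <- list(asymptote = mean(ipar), rate = NA_real_, ser = 0,
                n = length(cv), fitted = rep(mean(ipar), length(cv)),
                data = tibble::tibble(cv = cv, ipar = ipar),
                degenerate = TRUE)
    return(structure(out, class = "light_fit"))
  }
  a0 <- min(max(max(ipar), 0.05), 0.99)  # strictly inside the (0, 1] box
  pos <- cv > 0 & ipar < a0
  b0 <- stats::median(-log(pmax(1 - ipar[pos] / a0, 1e-6)) / cv[pos])
  b0 <- max(b0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(ipar ~ a * (1 - exp(-b * cv)),
                      data = data.frame(cv = cv, ipar = ipar),
                      start = list(a = a0, b = b0),
                      lower = c(a = 1e-6, b = 1e-6), upper = c(a = 1, b = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("light-interception fit did not converge (starts a=",
                             signif(a0, 3), ", b=", signif(b0, 3), "): ",
                             conditionMessage(e)))
  cf <- coef(fit)
  fitted <- cf[["a"]] * (1 - exp(-cf[["b"]] * cv))
  out <- list(asymptote = cf[["a"]], rate = cf[["b"]],
              ser = ser(ipar, fitted, p = 2), n = length(cv),
              fitted = fitted, data = tibble::tibble(cv = cv, ipar = ipar),
              degenerate = FALSE)
  structure(out, class = "light_fit")
}

#' @export
print.light_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<light_fit> degenerate: constant response, rate unidentifiable\n")
  } else {
    cat(sprintf("<light_fit> IPARf = %.4f (1 - exp(-%.4f CV)), SER = %.4f, n = %d\n",
                x$asymptote, x$rate, x$ser, x$n))
  }
  invisible(x)
}

#' @export
tidy.light_fit <- function(x, ...) {
  tibble::tibble(term = c("asymptote", "rate"),
                 estimate = c(x$asymptote, x$rate))
}

#' @export
glance.light_fit <- function(x, ...) {
  tibble::tibble(ser = x$ser, n = x$n, degenerate = x$degenerate)
}

#' @export
autoplot.light_fit <- function(object, ...) {
  grid <- tibble::tibble(cv = seq(0, max(object$data$cv), length.out = 200))
  grid$ipar <- object$asymptote * (1 - exp(-(object$rate %||% 0) * grid$cv))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$cv, y = .data$ipar)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = expression(CV ~ (m^3)), y = expression(IPAR[f]))
}
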