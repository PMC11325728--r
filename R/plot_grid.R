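#' Field layout description
#'
#' Geometry of a row-crop breeding field: `n_rows` crop rows, each holding
#' `plots_per_row` single-row plots of `plot_length` (m) along the row axis,
#' separated along the row by bare-soil alleys of `alley_width` (m); rows are
#' `row_spacing` (m) apart. The row axis points along +X rotated by
#' `row_axis_bearing` degrees (counter-clockwise).
#'
#' Defaults reproduce an 8 x 11 cotton breeding field with 3.05 m plots,
#' 1.83 m row spacing and 1.52 m alleys (about 50 m x 15 m).
#'
#' @param n_rows,plots_per_row Grid dimensions.
#' @param plot_length,row_spacing,alley_width Spacings in meters, all > 0.
#' @param row_axis_bearing Row-axis bearing in degrees.
#' @export
field_layout <- function(n_rows = 8, plots_per_row = 11, plot_length = 3.05,
                         row_spacing = 1.83, alley_width = 1.52,
                         row_axis_bearing = 0) {
  stopifnot(n_rows >= 1, plots_per_row >= 1,
            plot_length > 0, row_spacing > 0, alley_width > 0)
  structure(list(n_rows = as.integer(n_rows),
                 plots_per_row = as.integer(plots_per_row),
                 plot_length = plot_length, row_spacing = row_spacing,
                 alley_width = alley_width,
                 row_axis_bearing = row_axis_bearing),
            class = "field_layout")
}

# Pitch between consecutive plot centers along the row axis.
plot_pitch <- function(layout) layout$plot_length + layout$alley_width

# Unrotated plot centers; row i advances along +Y, plot j along +X.
layout_centers <- function(layout) {
  grid <- expand.grid(col = seq_len(layout$plots_per_row),
                      row = seq_len(layout$n_rows))
  cx <- (grid$col - 0.5) * plot_pitch(layout)
  cy <- (grid$row - 0.5) * layout$row_spacing
  b <- layout$row_axis_bearing * pi / 180
  tibble::tibble(
    row = grid$row, col = grid$col,
    cx = cos(b) * cx - sin(b) * cy,
    cy = sin(b) * cx + cos(b) * cy)
}

# Axis-aligned bounding box of the field (before bearing rotation), with margin.
layout_extent <- function(layout, margin = 1) {
  ctr <- layout_centers(layout)
  half <- max(plot_pitch(layout), layout$row_spacing) / 2
  c(xmin = min(ctr$cx) - half - margin, xmax = max(ctr$cx) + half + margin,
    ymin = min(ctr$cy) - half - margin, ymax = max(ctr$cy) + half + margin)
}

plot_id_for <- function(row, col) sprintf("P%d%02d", row, col)

#' Build a plot grid by replicating a first region of interest
#'
#' Mirrors the usual field-segmentation workflow: a rectangular region of
#' interest (ROI) is drawn around the first plot once, then rigidly
#' replicated at the layout's along-row pitch (`plot_length + alley_width`)
#' and row spacing to cover the whole field. The grid is a one-time artifact
#' reused for every registered session.
#'
#' @param first_roi Rectangle for the row-1, plot-1 ROI: a list with
#'   `cx`, `cy` (center, m), `length` (along-row, m), `width` (across-row,
#'   m) and optional `bearing_deg`.
#' @param layout A [field_layout()]; its bearing is ignored in favor of the
#'   ROI's when the ROI carries one.
#' @return A `plot_grid` tibble: one rectangle per plot with columns
#'   `plot_id`, `row`, `col`, `cx`, `cy`, `length`, `width`, `bearing_deg`,
#'   `genotype`, `replicate`.
#' @export
replicate_roi <- function(first_roi, layout) {
  stopifnot(is.list(first_roi), all(c("cx", "cy", "length", "width") %in% names(first_roi)))
  bearing <- first_roi$bearing_deg %||% layout$row_axis_bearing
  b <- bearing * pi / 180
  grid <- expand.grid(col = seq_len(layout$plots_per_row),
                      row = seq_len(layout$n_rows))
  # offsets in the row-axis frame, rotated into world XY
  ox <- (grid$col - 1) * plot_pitch(layout)
  oy <- (grid$row - 1) * layout$row_spacing
  out <- tibble::tibble(
    plot_id = plot_id_for(grid$row, grid$col),
    row = grid$row, col = grid$col,
    cx = first_roi$cx + cos(b) * ox - sin(b) * oy,
    cy = first_roi$cy + sin(b) * ox + cos(b) * oy,
    length = first_roi$length, width = first_roi$width,
    bearing_deg = bearing,
    genotype = NA_character_, replicate = NA_character_)
  new_plot_grid(out)
}

#' Plot grid for a field layout
#'
#' Convenience wrapper around [replicate_roi()] with the first ROI centered
#' on the first plot and spanning the full plot pitch and row spacing (so
#' the rectangles tile the field without overlap).
#'
#' @param layout A [field_layout()].
#' @param genotypes Optional tibble with `plot_id`, `genotype`, `replicate`
#'   columns to join onto the grid.
#' @export
layout_plot_grid <- function(layout, genotypes = NULL) {
  first <- list(cx = plot_pitch(layout) / 2, cy = layout$row_spacing / 2,
                length = plot_pitch(layout), width = layout$row_spacing,
                bearing_deg = layout$row_axis_bearing)
  # centers must match layout_centers in the rotated frame
  b <- layout$row_axis_bearing * pi / 180
  cxy <- c(cos(b) * first$cx - sin(b) * first$cy,
           sin(b) * first$cx + cos(b) * first$cy)
  first$cx <- cxy[1]; first$cy <- cxy[2]
  grid <- replicate_roi(first, layout)
  if (!is.null(genotypes)) {
    grid$genotype <- NULL; grid$replicate <- NULL
    grid <- dplyr::left_join(grid,
      dplyr::select(genotypes, "plot_id", "genotype", "replicate"),
      by = "plot_id")
  }
  new_plot_grid(grid)
}

new_plot_grid <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$plot_id)) stop("plot ids must be unique")
  check_grid_overlap(df)
  class(df) <- unique(c("plot_grid", class(df)))
  df
}

# Corner coordinates (4 x 2, counter-clockwise from the lower-left corner in
# the plot's local frame) for row `i` of the grid.
plot_corners <- function(grid, i) {
  b <- grid$bearing_deg[i] * pi / 180
  hl <- grid$length[i] / 2; hw <- grid$width[i] / 2
  local <- rbind(c(-hl, -hw), c(hl, -hw), c(hl, hw), c(-hl, hw))
  rot <- matrix(c(cos(b), sin(b), -sin(b), cos(b)), 2, 2)
  sweep(local %*% t(rot), 2, c(grid$cx[i], grid$cy[i]), "+")
}

# Separating-axis overlap test for two rotated rectangles.
rects_overlap <- function(grid, i, j, eps = 1e-9) {
  ci <- plot_corners(grid, i); cj <- plot_corners(grid, j)
  axes <- rbind(ci[2, ] - ci[1, ], ci[4, ] - ci[1, ],
                cj[2, ] - cj[1, ], cj[4, ] - cj[1, ])
  for (k in seq_len(nrow(axes))) {
    ax <- axes[k, ] / sqrt(sum(axes[k, ]^2))
    pi_ <- ci %*% ax; pj <- cj %*% ax
    if (max(pi_) <= min(pj) + eps || max(pj) <= min(pi_) + eps) return(FALSE)
  }
  TRUE
}

check_grid_overlap <- function(grid) {
  n <- nrow(grid)
  if (n < 2) return(invisible(TRUE))
  # bounding-circle prefilter keeps this O(n) in practice
  rad <- sqrt(grid$length^2 + grid$width^2) / 2
  for (i in seq_len(n - 1)) {
    near <- which(
      (grid$cx[-seq_len(i)] - grid$cx[i])^2 + (grid$cy[-seq_len(i)] - grid$cy[i])^2 <
        (rad[-seq_len(i)] + rad[i])^2) + i
    for (j in near) {
      if (rects_overlap(grid, i, j)) {
        stop(sprintf("plot polygons overlap: %s and %s",
                     grid$plot_id[i], grid$plot_id[j]))
      }
    }
  }
  invisible(TRUE)
}

#' Write / read a plot grid as GeoJSON
#'
#' The grid's canonical on-disk form: a `FeatureCollection` of closed
#' polygon rings with `plot_id`, `genotype`, `replicate`, `row`, `col`
#' properties. Coordinates are in the local metric field frame.
#'
#' @param grid A `plot_grid`.
#' @param path File path.
#' @export
write_plot_grid <- function(grid, path) {
  features <- purrr::map(seq_len(nrow(grid)), function(i) {
    corners <- plot_corners(grid, i)
    ring <- rbind(corners, corners[1, , drop = FALSE])
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ]))),
      properties = list(plot_id = grid$plot_id[i],
                        row = grid$row[i], col = grid$col[i],
                        genotype = grid$genotype[i],
                        replicate = grid$replicate[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_plot_grid
#' @export
read_plot_grid <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) stop("not a GeoJSON FeatureCollection")
  rows <- purrr::map(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) stop("plot grid features must be polygons")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    if (nrow(ring) != 4) stop("plot polygons must be quadrilaterals")
    ctr <- colMeans(ring)
    e1 <- ring[2, ] - ring[1, ]; e2 <- ring[4, ] - ring[1, ]
    p <- f$properties
    tibble::tibble(
      plot_id = as.character(p$plot_id),
      row = as.integer(p$row %||% NA), col = as.integer(p$col %||% NA),
      cx = ctr[1], cy = ctr[2],
      length = sqrt(sum(e1^2)), width = sqrt(sum(e2^2)),
      bearing_deg = atan2(e1[2], e1[1]) * 180 / pi,
      genotype = as.character(p$genotype %||% NA),
      replicate = as.character(p$replicate %||% NA))
  })
  new_plot_grid(dplyr::bind_rows(rows))
}

#' @export
print.plot_grid <- function(x, ...) {
  cat(sprintf("<plot_grid> %d plots (%d x %d), plot %.2f x %.2f m, bearing %.1f deg\n",
              nrow(x), max(x$row), max(x$col), x$length[1], x$width[1],
              x$bearing_deg[1]))
  NextMethod()
}

# Indices of points whose XY falls inside rectangle i; half-open on the
# upper/right edges so boundary points belong to exactly one plot.
points_in_plot <- function(grid, i, x, y) {
  b <- grid$bearing_deg[i] * pi / 180
  dx <- x - grid$cx[i]; dy <- y - grid$cy[i]
  lx <- cos(b) * dx + sin(b) * dy
  ly <- -sin(b) * dx + cos(b) * dy
  hl <- grid$length[i] / 2; hw <- grid$width[i] / 2
  which(lx >= -hl & lx < hl & ly >= -hw & ly < hw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
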