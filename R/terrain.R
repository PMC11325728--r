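#' Gridded terrain model
#'
#' A digital terrain model (DTM): ground elevations on a regular XY grid.
#' Cells are indexed `(row, col) = (+y, +x)` with 0-based origin at
#' `origin`; the center of cell `(i, j)` (1-based R indexing) is at
#' `origin + (j - 1/2, i - 1/2) * cell_size`.
#'
#' @param origin Length-2 numeric, XY of the grid's lower-left corner (m).
#' @param cell_size Cell edge length (m), > 0.
#' @param elevations Numeric matrix of ground elevations (m); rows advance
#'   along +y, columns along +x. `NA` marks gap cells (no ground data yet).
#' @return An object of class `terrain_model`.
#' @export
terrain_model <- function(origin, cell_size, elevations) {
  stopifnot(length(origin) == 2, cell_size > 0, is.matrix(elevations))
  structure(list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
                 elevations = elevations),
            class = "terrain_model")
}

#' @export
print.terrain_model <- function(x, ...) {
  rng <- range(x$elevations, na.rm = TRUE)
  cat(sprintf(
    "<terrain_model> %d x %d cells of %.3g m, origin (%.2f, %.2f), z in [%.3f, %.3f] m, %d gap cells\n",
    nrow(x$elevations), ncol(x$elevations), x$cell_size,
    x$origin[1], x$origin[2], rng[1], rng[2], sum(is.na(x$elevations))))
  invisible(x)
}

#' Interpolate terrain elevation
#'
#' Bilinear interpolation between cell centers; queries outside the grid are
#' clamped to the border cells (nearest-cell extrapolation). Gap cells must
#' have been filled (see [reconstruct_dtm()]).
#'
#' @param terrain A `terrain_model`.
#' @param x,y Query coordinates (vectors, meters).
#' @return Elevations (meters).
#' @export
terrain_height <- function(terrain, x, y) {
  z <- terrain$elevations
  if (anyNA(z)) stop("terrain model has unfilled gap cells")
  nr <- nrow(z); nc <- ncol(z)
  # continuous cell-center coordinates (1-based)
  cx <- (x - terrain$origin[1]) / terrain$cell_size + 0.5
  cy <- (y - terrain$origin[2]) / terrain$cell_size + 0.5
  cx <- pmin(pmax(cx, 1), nc)
  cy <- pmin(pmax(cy, 1), nr)
  j0 <- pmin(floor(cx), nc - 1); j0 <- pmax(j0, 1)
  i0 <- pmin(floor(cy), nr - 1); i0 <- pmax(i0, 1)
  if (nc == 1) { j0 <- rep(1, length(cx)); fx <- rep(0, length(cx)) } else fx <- cx - j0
  if (nr == 1) { i0 <- rep(1, length(cy)); fy <- rep(0, length(cy)) } else fy <- cy - i0
  z00 <- z[cbind(i0, j0)]
  z01 <- z[cbind(i0, pmin(j0 + 1, nc))]
  z10 <- z[cbind(pmin(i0 + 1, nr), j0)]
  z11 <- z[cbind(pmin(i0 + 1, nr), pmin(j0 + 1, nc))]
  (1 - fy) * ((1 - fx) * z00 + fx * z01) + fy * ((1 - fx) * z10 + fx * z11)
}

# TRUE where the query XY lies inside the grid's coverage.
terrain_covers <- function(terrain, x, y) {
  nrk <- dim(terrain$elevations)
  xmax <- terrain$origin[1] + nrk[2] * terrain$cell_size
  ymax <- terrain$origin[2] + nrk[1] * terrain$cell_size
  x >= terrain$origin[1] & x <= xmax & y >= terrain$origin[2] & y <= ymax
}

#' Terrain model cell centers as a point cloud
#'
#' Used as the "terrain points" fed to the ICP rough-alignment phase.
#'
#' @param terrain A `terrain_model`.
#' @export
terrain_points <- function(terrain) {
  z <- terrain$elevations
  nr <- nrow(z); nc <- ncol(z)
  xs <- terrain$origin[1] + (seq_len(nc) - 0.5) * terrain$cell_size
  ys <- terrain$origin[2] + (seq_len(nr) - 0.5) * terrain$cell_size
  keep <- !is.na(z)
  point_cloud(x = rep(xs, each = nr)[keep], y = rep(ys, times = nc)[keep],
              z = z[keep])
}

#' Export / import a terrain model as an ASCII grid
#'
#' Plain-text format for inspection and interchange: a 3-line header
#' (`origin`, `cell_size`, `dim`) followed by the elevation matrix, one grid
#' row per line, `NA` for gaps.
#'
#' @param terrain A `terrain_model`.
#' @param path File path.
#' @export
write_terrain <- function(terrain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("origin %.10g %.10g", terrain$origin[1], terrain$origin[2]),
    sprintf("cell_size %.10g", terrain$cell_size),
    sprintf("dim %d %d", nrow(terrain$elevations), ncol(terrain$elevations))
  ), con)
  write.table(terrain$elevations, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_terrain
#' @export
read_terrain <- function(path) {
  lines <- readLines(path, n = 3)
  origin <- as.numeric(strsplit(lines[1], " ")[[1]][2:3])
  cell_size <- as.numeric(strsplit(lines[2], " ")[[1]][2])
  dims <- as.integer(strsplit(lines[3], " ")[[1]][2:3])
  z <- as.matrix(read.table(path, skip = 3))
  dimnames(z) <- NULL
  stopifnot(all(dim(z) == dims))
  terrain_model(origin, cell_size, z)
}
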