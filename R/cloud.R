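#' Construct a point cloud
#'
#' A point cloud is an ordinary tibble with numeric `x`, `y`, `z` columns
#' (meters, right-handed frame, Z up). Any further columns are carried along
#' as per-point attributes, so clouds compose with the usual dplyr verbs.
#'
#' @param x,y,z Numeric vectors of equal length (meters).
#' @param ... Further equal-length per-point attribute vectors.
#' @return A tibble with class `tls_cloud` prepended.
#' @examples
#' pc <- point_cloud(x = runif(10), y = runif(10), z = 0)
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(), ...) {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z), ...)
  if (anyNA(out$x) || anyNA(out$y) || anyNA(out$z) ||
      any(!is.finite(c(out$x, out$y, out$z)))) {
    stop("point cloud coordinates must be finite")
  }
  as_point_cloud(out)
}

#' Coerce to a point cloud
#'
#' @param obj A data frame with `x`, `y`, `z` columns, or a numeric matrix
#'   with at least three columns (taken as x, y, z).
#' @return A `tls_cloud` tibble.
#' @export
as_point_cloud <- function(obj) {
  if (is.matrix(obj)) {
    stopifnot(ncol(obj) >= 3)
    obj <- tibble::tibble(x = obj[, 1], y = obj[, 2], z = obj[, 3])
  }
  stopifnot(all(c("x", "y", "z") %in% names(obj)))
  out <- tibble::as_tibble(obj)
  class(out) <- unique(c("tls_cloud", class(out)))
  out
}

#' @export
is_point_cloud <- function(obj) {
  is.data.frame(obj) && all(c("x", "y", "z") %in% names(obj))
}

# Coordinates as an N x 3 matrix (internal currency for the C++ kernels).
cloud_matrix <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

#' Number of points in a cloud
#' @param cloud A point cloud.
#' @export
n_points <- function(cloud) nrow(cloud)

#' Bird's-eye scatter of a point cloud, colored by height
#'
#' @param cloud A point cloud.
#' @param max_points Decimate to at most this many points before plotting.
#' @return A ggplot object.
#' @export
plot_cloud_bev <- function(cloud, max_points = 5e4) {
  if (nrow(cloud) > max_points) {
    cloud <- cloud[seq(1, nrow(cloud), length.out = max_points), ]
  }
  ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$z)) +
    ggplot2::geom_point(size = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "z [m]") +
    ggplot2::labs(x = "x [m]", y = "y [m]")
}
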