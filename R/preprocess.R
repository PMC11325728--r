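#' Statistical outlier removal (SOR)
#'
#' Computes each point's mean distance to its `n_neighbors` nearest
#' neighbors and keeps the points whose statistic lies within
#' `mean +/- std_ratio * sd` of that statistic's distribution over the whole
#' cloud. The defaults (20 neighbors, 2.5 standard deviations) are the usual
#' denoising setting for multi-scan TLS field data.
#'
#' @param cloud A point cloud.
#' @param n_neighbors Number of neighbors in the distance statistic.
#' @param std_ratio Width of the acceptance band in standard deviations.
#' @return The filtered cloud. Clouds with `n_neighbors` points or fewer are
#'   returned unchanged with a warning.
#' @export
sor_filter <- function(cloud, n_neighbors = 20, std_ratio = 2.5) {
  if (nrow(cloud) <= n_neighbors) {
    warning("cloud smaller than n_neighbors + 1; returned unchanged")
    return(cloud)
  }
  d <- cpp_knn_mean_dist(cloud_matrix(cloud), as.integer(n_neighbors))
  mu <- mean(d)
  s <- sd(d)
  tol <- 1e-9 * mu  # closed band up to numerical noise
  keep <- d >= mu - std_ratio * s - tol & d <= mu + std_ratio * s + tol
  cloud[keep, ]
}

#' Distance-based subsampling
#'
#' Greedy thinning in input order: a point is retained iff it lies at least
#' `d` from every previously retained point. Every removed point is
#' therefore within `d` of a retained one, and all retained pairs are
#' `>= d` apart. Deterministic and O(N) via a spatial hash. The 5 mm
#' default matches the usual point-to-point threshold for TLS crop data.
#'
#' @param cloud A point cloud.
#' @param d Minimum point-to-point distance (m), > 0.
#' @export
subsample_min_distance <- function(cloud, d = 0.005) {
  stopifnot(d > 0)
  if (nrow(cloud) == 0) return(cloud)
  keep <- cpp_min_dist_subsample(cloud_matrix(cloud), d)
  cloud[keep, ]
}

#' Reconstruct a digital terrain model from a point cloud
#'
#' Rasterize-then-fill ground estimation: the cloud is binned on a regular
#' XY grid and the per-cell ground elevation is taken as the 5th percentile
#' of the in-cell z values (robust against low outliers while tracking the
#' lowest returns). Cells without any points are marked as gaps and filled
#' by inverse-distance-weighted interpolation from the nearest valid cells;
#' queries beyond the border fall back to nearest-cell extrapolation (see
#' [terrain_height()]).
#'
#' Under a dense canopy no true ground returns survive, so the 5th
#' percentile rides up into the vegetation: the reconstruction then
#' overestimates the terrain there. This failure mode is intrinsic to
#' rasterized ground estimation from above-canopy scans and is exercised
#' deliberately by the synthetic occlusion tests.
#'
#' @param cloud A non-empty point cloud.
#' @param cell_size Raster cell size (m), default 10 cm.
#' @param probs Percentile of in-cell z used as the ground estimate.
#' @param min_points Minimum in-cell points for a valid ground estimate.
#' @return A [terrain_model()] with all gaps filled.
#' @export
reconstruct_dtm <- function(cloud, cell_size = 0.10, probs = 0.05,
                            min_points = 1) {
  if (nrow(cloud) == 0) stop("insufficient terrain data: empty cloud")
  origin <- c(min(cloud$x), min(cloud$y))
  j <- pmin(floor((cloud$x - origin[1]) / cell_size),
            ceiling((max(cloud$x) - origin[1]) / cell_size) - 1)
  i <- pmin(floor((cloud$y - origin[2]) / cell_size),
            ceiling((max(cloud$y) - origin[2]) / cell_size) - 1)
  nc <- max(j) + 1L
  nr <- max(i) + 1L
  cell <- i + nr * j  # column-major cell index
  est <- tapply(cloud$z, cell, function(v)
    if (length(v) >= min_points) quantile(v, probs, names = FALSE) else NA_real_)
  z <- matrix(NA_real_, nr, nc)
  z[as.integer(names(est)) + 1L] <- est
  if (!any(!is.na(z))) stop("insufficient terrain data")
  terrain_model(origin, cell_size, fill_terrain_gaps(z, cell_size))
}

# Fill NA cells by inverse-distance-weighted interpolation from the k
# nearest valid cell centers (kd-tree lookup in cell-index coordinates).
fill_terrain_gaps <- function(z, cell_size, k = 8) {
  gaps <- which(is.na(z), arr.ind = TRUE)
  if (nrow(gaps) == 0) return(z)
  valid <- which(!is.na(z), arr.ind = TRUE)
  kk <- min(k, nrow(valid))
  nn <- cpp_knn(cbind(gaps[, 2], gaps[, 1], 0),
                cbind(valid[, 2], valid[, 1], 0), kk)
  vz <- z[valid]
  w <- 1 / pmax(nn$dist, 0.5)^2
  zhat <- matrix(vz[nn$idx], nrow = nrow(gaps))
  filled <- z
  filled[gaps] <- rowSums(w * zhat) / rowSums(w)
  filled
}

#' Normalize point heights against a terrain model
#'
#' Replaces each point's elevation by its height above the terrain:
#' `z' = z - terrain(x, y)`. XY coordinates are unchanged. Points outside
#' the terrain's coverage use nearest-cell extrapolation, with a warning.
#'
#' @param cloud A point cloud.
#' @param terrain A [terrain_model()].
#' @export
normalize_heights <- function(cloud, terrain) {
  if (nrow(cloud) == 0) return(cloud)
  if (!all(terrain_covers(terrain, cloud$x, cloud$y))) {
    warning("points outside terrain coverage; using nearest-cell extrapolation")
  }
  cloud$z <- cloud$z - terrain_height(terrain, cloud$x, cloud$y)
  cloud
}

#' Standard per-session conditioning
#'
#' SOR denoising, distance subsampling, DTM reconstruction and local height
#' normalization in one call.
#'
#' @param cloud A raw session point cloud.
#' @param params A [pipeline_config()] (or its `preprocess` sub-list).
#' @return List with `cloud` (normalized), `raw` (denoised, unnormalized)
#'   and `terrain` (the session DTM).
#' @export
preprocess_session <- function(cloud, params = pipeline_config()$preprocess) {
  cloud <- sor_filter(cloud, params$sor_neighbors, params$sor_std_ratio)
  cloud <- subsample_min_distance(cloud, params$subsample_distance)
  terrain <- reconstruct_dtm(cloud, cell_size = params$dtm_cell_size)
  list(cloud = normalize_heights(cloud, terrain), raw = cloud, terrain = terrain)
}
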