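#' Terrain-based ICP rough alignment
#'
#' Point-to-point iterative closest point between two terrain point sets:
#' nearest-neighbor correspondences (rejected beyond `max_corr_dist`),
#' SVD-based rigid update, iterated until the RMS improvement drops below
#' `tol` or `max_iter` is reached. The initial transform plays the role of
#' the coarse scanner-pose guess that keeps ICP inside its convergence
#' basin.
#'
#' @param source_terrain_pts,ref_terrain_pts Point clouds (>= 100 points
#'   each), typically [terrain_points()] of the two sessions' DTMs.
#' @param init Initial `rigid_transform` applied to the source.
#' @param max_iter,tol Iteration cap and RMS-improvement tolerance (m).
#' @param max_corr_dist Correspondence rejection distance (m).
#' @return List with `transform` (source -> reference), final `rms` (m),
#'   `n_iter` and `converged`.
#' @export
icp_align_terrain <- function(source_terrain_pts, ref_terrain_pts,
                              init = rigid_transform(), max_iter = 100,
                              tol = 1e-6, max_corr_dist = 0.5) {
  if (nrow(source_terrain_pts) < 100 || nrow(ref_terrain_pts) < 100) {
    stop("ICP needs at least 100 points in each terrain cloud")
  }
  ref_m <- cloud_matrix(ref_terrain_pts)
  src0 <- cloud_matrix(source_terrain_pts)
  tf <- init
  rms_prev <- Inf
  n_worse <- 0
  rms <- NA_real_
  for (it in seq_len(max_iter)) {
    src <- src0 %*% t(tf$rotation)
    src <- sweep(src, 2, tf$translation, "+")
    nn <- cpp_nn1(src, ref_m)
    sel <- nn$dist <= max_corr_dist
    if (sum(sel) < 3) stop("ICP lost all correspondences (check the initial transform)")
    rms <- sqrt(mean(nn$dist[sel]^2))
    if (rms > rms_prev + 1e-12) {
      n_worse <- n_worse + 1
      if (n_worse >= 3) {
        stop(sprintf(
          "ICP diverging: rms grew 3 consecutive iterations (%.4f m at iteration %d)",
          rms, it))
      }
    } else n_worse <- 0
    if (rms_prev - rms < tol && it > 1) {
      return(list(transform = tf, rms = rms, n_iter = it, converged = TRUE))
    }
    rms_prev <- rms
    upd <- kabsch(src[sel, , drop = FALSE], ref_m[nn$idx[sel], , drop = FALSE])
    tf <- compose_transforms(upd, tf)
  }
  list(transform = tf, rms = rms, n_iter = max_iter, converged = FALSE)
}

# Least-squares rigid transform mapping src onto dst (paired rows).
kabsch <- function(src, dst) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  h <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(r, cd - as.numeric(r %*% cs))
}

#' Detect plot centroids in a bird's-eye view
#'
#' The fine-registration feature extractor. Pipeline: (1) vegetation mask
#' (`z > veg_threshold` on the height-normalized cloud); (2) occupancy
#' raster at `grid_resolution` and connected-component clustering; (3)
#' per-cluster re-threshold at half that cluster's maximum height, keeping
#' the upper canopy; (4) components recomputed on the upper-canopy raster;
#' (5) PCA filtering — a component is discarded when its first principal
#' axis deviates more than `max_axis_dev_deg` from the row axis, when its
#' along-row extent does not exceed its across-row extent, or when its area
#' falls outside `area_band` times the nominal cluster area (the session's
#' median component area unless `nominal_area` is given); (6) the surviving
#' components' pixel centroids are returned in world coordinates.
#'
#' @param normalized_cloud Height-normalized point cloud.
#' @param grid_resolution Raster pixel size (m).
#' @param row_axis_bearing Row-axis bearing (degrees).
#' @param veg_threshold Vegetation height cut (m).
#' @param max_axis_dev_deg Orientation gate on the first principal axis.
#' @param area_band Relative area acceptance band.
#' @param nominal_area Optional absolute nominal cluster area (m^2).
#' @return A `centroid_set` tibble: `x`, `y`, `area`, `len_major`,
#'   `len_minor`, `orientation_deg`, `n_pixels`.
#' @export
bev_extract_centroids <- function(normalized_cloud, grid_resolution = 0.05,
                                  row_axis_bearing = 0, veg_threshold = 0.05,
                                  max_axis_dev_deg = 30,
                                  area_band = c(0.25, 2),
                                  nominal_area = NULL) {
  veg <- normalized_cloud[normalized_cloud$z > veg_threshold, ]
  if (nrow(veg) == 0) stop("BEV extraction failed: no vegetation points")
  origin <- c(min(veg$x), min(veg$y))
  j <- floor((veg$x - origin[1]) / grid_resolution) + 1L
  i <- floor((veg$y - origin[2]) / grid_resolution) + 1L
  nr <- max(i); nc <- max(j)
  occ <- matrix(0, nr, nc)
  occ[cbind(i, j)] <- 1
  # morphological closing bridges single-pixel gaps so a plot's canopy forms
  # one component even at moderate point density
  kern <- EBImage::makeBrush(3, shape = "box")
  lab <- as.matrix(EBImage::bwlabel(EBImage::closing(occ, kern)))
  cl <- lab[cbind(i, j)]                       # coarse cluster per point
  # per-cluster half-max height cut
  zmax <- tapply(veg$z, cl, max)
  upper <- veg$z > zmax[as.character(cl)] / 2
  iu <- i[upper]; ju <- j[upper]
  occ2 <- matrix(0, nr, nc)
  occ2[cbind(iu, ju)] <- 1
  lab2 <- as.matrix(EBImage::bwlabel(EBImage::closing(occ2, kern)))
  n_comp <- max(lab2)
  if (n_comp == 0) stop("BEV extraction failed: no clusters above half-max")
  px <- which(lab2 > 0, arr.ind = TRUE)
  comp <- lab2[px]
  wx <- origin[1] + (px[, 2] - 0.5) * grid_resolution
  wy <- origin[2] + (px[, 1] - 0.5) * grid_resolution
  b <- row_axis_bearing * pi / 180
  along <- cos(b) * wx + sin(b) * wy
  across <- -sin(b) * wx + cos(b) * wy
  stats <- purrr::map(seq_len(n_comp), function(kk) {
    sel <- comp == kk
    n_px <- sum(sel)
    cx <- mean(wx[sel]); cy <- mean(wy[sel])
    if (n_px >= 3) {
      cv <- stats::cov(cbind(wx[sel], wy[sel]))
      eg <- eigen(cv, symmetric = TRUE)
      orient <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi
      lens <- 2 * sqrt(pmax(eg$values, 0))
    } else {
      orient <- NA_real_
      lens <- c(0, 0)
    }
    tibble::tibble(
      x = cx, y = cy, n_pixels = n_px,
      area = n_px * grid_resolution^2,
      len_major = lens[1], len_minor = lens[2],
      orientation_deg = orient,
      extent_along = diff(range(along[sel])) + grid_resolution,
      extent_across = diff(range(across[sel])) + grid_resolution)
  })
  st <- dplyr::bind_rows(stats)
  st <- st[st$n_pixels >= 4, ]                 # single-pixel specks are noise
  if (nrow(st) == 0) stop("BEV extraction failed: only speck clusters found")
  # nominal cluster area: the area of the component a typical canopy pixel
  # belongs to (pixel-weighted median), robust to many small fragments
  nominal <- nominal_area %||% weighted_median(st$area, st$n_pixels)
  dev <- abs(((st$orientation_deg - row_axis_bearing) + 90) %% 180 - 90)
  keep <- !is.na(st$orientation_deg) &
    dev <= max_axis_dev_deg &
    st$extent_along / st$extent_across >= 1 &
    st$area >= area_band[1] * nominal & st$area <= area_band[2] * nominal
  out <- st[keep, ]
  if (nrow(out) > 0) {
    # partial plots (broken canopies) sit off-center along the row; keep
    # only clusters of near-typical along-row extent
    ext_nom <- weighted_median(out$extent_along, out$n_pixels)
    out <- out[out$extent_along >= 0.6 * ext_nom, ]
  }
  if (nrow(out) == 0) stop("BEV extraction failed: no clusters survived filtering")
  class(out) <- unique(c("centroid_set", class(out)))
  out
}

#' Match centroid sets by mutual nearest neighbors
#'
#' Pairs a source centroid with a reference centroid when each is the
#' other's nearest neighbor and they lie within `max_match_dist`; all
#' unmatched (missing) centroids are excluded. Equidistant candidates are
#' resolved in favor of the lowest index, making the matching deterministic.
#'
#' @param source,ref `centroid_set` tibbles (or data frames with x/y).
#' @param max_match_dist Gate distance (m); keep below half the minimum plot
#'   spacing. Default 0.9 m (half of a 1.83 m row spacing).
#' @return A `matched_pairs` list: `k`, `ref` and `src` k x 2 matrices,
#'   plus the contributing indices.
#' @export
match_centroids_knn <- function(source, ref, max_match_dist = 0.9) {
  sm <- cbind(source$x, source$y)
  rm_ <- cbind(ref$x, ref$y)
  d <- outer(sm[, 1], rm_[, 1], "-")^2 + outer(sm[, 2], rm_[, 2], "-")^2
  nn_of_src <- apply(d, 1, which.min)          # ties -> lowest index
  nn_of_ref <- apply(d, 2, which.min)
  src_idx <- which(nn_of_ref[nn_of_src] == seq_len(nrow(sm)))
  ref_idx <- nn_of_src[src_idx]
  ok <- sqrt(d[cbind(src_idx, ref_idx)]) <= max_match_dist
  src_idx <- src_idx[ok]; ref_idx <- ref_idx[ok]
  if (length(src_idx) < 3) {
    stop(sprintf("insufficient correspondences: %d matched pairs (need >= 3)",
                 length(src_idx)))
  }
  structure(list(k = length(src_idx),
                 ref = rm_[ref_idx, , drop = FALSE],
                 src = sm[src_idx, , drop = FALSE],
                 ref_idx = ref_idx, src_idx = src_idx),
            class = "matched_pairs")
}

#' Planar Procrustes superimposition of matched centroids
#'
#' Closed-form least-squares rigid 2D alignment (no scaling): the optimal
#' translation is the difference of the two centers of gravity; after
#' centering both sets at the origin, the rotation angle comes from the
#' sums of cross and dot products,
#' `theta = atan2(sum(x_s y_r - y_s x_r), sum(x_r x_s + y_r y_s))`,
#' which minimizes the sum of squared distances between corresponding
#' points. The returned `transform2d` acts as rotate-about-origin followed
#' by translation.
#'
#' @param pairs A `matched_pairs` object (k >= 2).
#' @return A [transform2d()] mapping source points onto the reference.
#' @export
procrustes_align <- function(pairs) {
  stopifnot(inherits(pairs, "matched_pairs"))
  if (pairs$k < 2) stop("need at least 2 matched pairs")
  cr <- colMeans(pairs$ref)
  cs <- colMeans(pairs$src)
  rs <- sweep(pairs$ref, 2, cr)
  ss <- sweep(pairs$src, 2, cs)
  num <- sum(ss[, 1] * rs[, 2] - ss[, 2] * rs[, 1])
  den <- sum(rs[, 1] * ss[, 1] + rs[, 2] * ss[, 2])
  if (abs(num) < 1e-15 && abs(den) < 1e-15) {
    warning("degenerate centroid configuration; translation-only alignment")
    theta <- 0
  } else {
    theta <- atan2(num, den)
  }
  ct <- cos(theta); st <- sin(theta)
  tx <- cr[1] - (ct * cs[1] - st * cs[2])
  ty <- cr[2] - (st * cs[1] + ct * cs[2])
  transform2d(tx, ty, theta)
}

#' Two-phase registration of a session pair
#'
#' Phase 1 aligns the two sessions' terrain models with ICP; phase 2
#' refines the planar alignment by matching plot centroids detected in a
#' bird's-eye view of the height-normalized clouds and solving a Procrustes
#' superimposition. The planar refinement is lifted to SE(3) (rotation
#' about +Z, zero Z-translation) and composed with the phase-1 transform.
#' If the BEV step fails (e.g. no usable clusters late in the season), the
#' phase-1 transform is returned flagged `"coarse_only"`.
#'
#' @param source,ref Preprocessed (denoised, subsampled, unnormalized)
#'   session clouds.
#' @param source_terrain,ref_terrain The sessions' [terrain_model()]s.
#' @param params `registration` sub-list of [pipeline_config()].
#' @return List with `transform` (source -> reference frame), `phase`
#'   (`"refined"` or `"coarse_only"`), `icp` (phase-1 detail), `bev`
#'   (the `transform2d`, or NULL) and `n_pairs`.
#' @export
register_pair <- function(source, ref, source_terrain, ref_terrain,
                          params = pipeline_config()$registration) {
  icp <- icp_align_terrain(terrain_points(source_terrain),
                           terrain_points(ref_terrain),
                           init = params$init %||% rigid_transform(),
                           max_iter = params$icp_max_iter,
                           tol = params$icp_tol,
                           max_corr_dist = params$icp_max_corr_dist)
  src1 <- apply_transform(source, icp$transform)
  refine <- tryCatch({
    refn <- suppressWarnings(normalize_heights(ref, ref_terrain))
    srcn <- suppressWarnings(normalize_heights(src1, ref_terrain))
    c_ref <- bev_extract_centroids(refn, params$bev_resolution,
                                   params$row_axis_bearing,
                                   params$bev_veg_threshold)
    c_src <- bev_extract_centroids(srcn, params$bev_resolution,
                                   params$row_axis_bearing,
                                   params$bev_veg_threshold)
    pairs <- match_centroids_knn(c_src, c_ref, params$knn_gate)
    t2 <- procrustes_align(pairs)
    # robust refinement: re-match after the first solve with a tightened
    # gate, then drop high-residual pairs (fragmented or weed clusters give
    # displaced centroids that would bias the rotation) and re-solve
    for (round in 1:2) {
      c_src_t <- c_src
      xy <- apply_transform2d(cbind(c_src$x, c_src$y), t2)
      c_src_t$x <- xy[, 1]; c_src_t$y <- xy[, 2]
      pairs <- match_centroids_knn(c_src_t, c_ref,
                                   min(params$knn_gate, 0.35))
      res <- sqrt(rowSums((pairs$ref - pairs$src)^2))
      keep <- res <= max(2 * stats::median(res), 0.02)
      if (sum(keep) < 3) keep <- rep(TRUE, pairs$k)
      pairs_t <- structure(list(k = sum(keep),
                                ref = pairs$ref[keep, , drop = FALSE],
                                src = pairs$src[keep, , drop = FALSE]),
                           class = "matched_pairs")
      t2 <- compose_transform2d(procrustes_align(pairs_t), t2)
    }
    list(t2 = t2, n_pairs = pairs$k)
  }, error = function(e) e)
  if (inherits(refine, "error")) {
    return(list(transform = icp$transform, phase = "coarse_only",
                icp = icp, bev = NULL, n_pairs = 0L,
                bev_error = conditionMessage(refine)))
  }
  list(transform = compose_transforms(lift_transform2d(refine$t2), icp$transform),
       phase = "refined", icp = icp, bev = refine$t2, n_pairs = refine$n_pairs)
}

#' Renormalize registered sessions against one reference terrain
#'
#' After spatial registration, all sessions' heights are re-expressed
#' relative to the single reference-session terrain (global ground level
#' Z = 0), discarding the per-session local normalizations and removing
#' cross-session height bias.
#'
#' @param clouds List of registered point clouds.
#' @param reference_terrain The reference session's [terrain_model()].
#' @export
global_renormalize <- function(clouds, reference_terrain) {
  purrr::map(clouds, normalize_heights, terrain = reference_terrain)
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}
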