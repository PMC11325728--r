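#' Directed and symmetric Hausdorff distance
#'
#' `hausdorff_directed(A, B)` is `max over a in A` of the distance from `a`
#' to its nearest neighbor in `B`; the symmetric variant is the larger of
#' the two directed values.
#'
#' @param a,b Non-empty point clouds.
#' @return Distance in meters.
#' @export
hausdorff_directed <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("Hausdorff distance needs non-empty clouds")
  max(cpp_nn1(cloud_matrix(a), cloud_matrix(b))$dist)
}

#' @rdname hausdorff_directed
#' @export
hausdorff_symmetric <- function(a, b) {
  max(hausdorff_directed(a, b), hausdorff_directed(b, a))
}

#' Registration quality report
#'
#' Nearest-neighbor residual diagnostics from a registered cloud to its
#' reference: the RMS and standard deviation of the residual norms, the
#' directed Hausdorff distance, and per-axis extrema of the signed residual
#' components (registered minus nearest reference point). All values in
#' meters; multiply by 100 for the conventional centimeter reporting.
#'
#' @param registered,reference_aligned Point clouds in the same frame.
#' @param phase `"refined"` or `"coarse_only"`, carried into the report.
#' @param symmetric Use the symmetric Hausdorff distance instead of the
#'   directed (registered -> reference) default.
#' @return A one-row `registration_report` tibble.
#' @export
registration_report <- function(registered, reference_aligned,
                                phase = "refined", symmetric = FALSE) {
  if (nrow(registered) == 0 || nrow(reference_aligned) == 0) {
    stop("registration report needs non-empty clouds")
  }
  qm <- cloud_matrix(registered)
  tm <- cloud_matrix(reference_aligned)
  nn <- cpp_nn1(qm, tm)
  res <- qm - tm[nn$idx, , drop = FALSE]
  norms <- sqrt(rowSums(res^2))
  dh <- if (symmetric) {
    max(max(norms), hausdorff_directed(reference_aligned, registered))
  } else max(norms)
  out <- tibble::tibble(
    rms = sqrt(mean(norms^2)),
    rms_sd = sd(norms),
    hausdorff = dh,
    dhx_max = max(res[, 1]), dhx_min = min(res[, 1]),
    dhy_max = max(res[, 2]), dhy_min = min(res[, 2]),
    dhz_max = max(res[, 3]), dhz_min = min(res[, 3]),
    n_points_compared = nrow(registered),
    phase = phase)
  class(out) <- unique(c("registration_report", class(out)))
  out
}

#' Summarize a series of registration reports
#'
#' Binds per-session reports into one table with values in centimeters,
#' mirroring the usual per-session error-table layout (RMS with its spread,
#' overall and per-axis Hausdorff extrema).
#'
#' @param reports Named list of `registration_report` rows (names = session
#'   labels, e.g. DAP).
#' @export
report_table <- function(reports) {
  tb <- dplyr::bind_rows(reports, .id = "session")
  num <- c("rms", "rms_sd", "hausdorff", "dhx_max", "dhx_min",
           "dhy_max", "dhy_min", "dhz_max", "dhz_min")
  tb[num] <- lapply(tb[num], function(v) round(v * 100, 2))  # m -> cm
  tb
}
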