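# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. Everything here is deliberately naive O(N^2) code.

# all pairwise Euclidean distances between the rows of two matrices
bf_cross_dist <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
}

bf_nn_dist <- function(query, target) {
  apply(bf_cross_dist(query, target), 1, min)
}

bf_hausdorff <- function(a, b) {
  max(bf_nn_dist(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")])))
}

# SOR filter by direct enumeration: mean distance to k nearest neighbors,
# band mean +/- ratio * sd
bf_sor_keep <- function(cloud, k, ratio) {
  m <- as.matrix(cloud[, c("x", "y", "z")])
  d <- bf_cross_dist(m, m)
  diag(d) <- Inf
  stat <- apply(d, 1, function(v) mean(sort(v)[seq_len(k)]))
  tol <- 1e-9 * mean(stat)
  stat >= mean(stat) - ratio * sd(stat) - tol &
    stat <= mean(stat) + ratio * sd(stat) + tol
}

# sum of squared distances after applying a planar transform to src
ssd2d <- function(ref, src, tf) {
  sum((ref - tls4d::apply_transform2d(src, tf))^2)
}

# brute-force planar alignment: centroid translation at each angle of a
# hierarchical theta grid (coarse pass, then 1e-4 degree refinement)
bf_procrustes <- function(ref, src, theta_range = 6 * pi / 180) {
  cr <- colMeans(ref)
  cs <- colMeans(src)
  eval_theta <- function(theta) {
    ct <- cos(theta); st <- sin(theta)
    tx <- cr[1] - (ct * cs[1] - st * cs[2])
    ty <- cr[2] - (st * cs[1] + ct * cs[2])
    ssd2d(ref, src, tls4d::transform2d(tx, ty, theta))
  }
  coarse <- seq(-theta_range, theta_range, by = 1e-4)
  s1 <- vapply(coarse, eval_theta, numeric(1))
  t1 <- coarse[which.min(s1)]
  fine <- seq(t1 - 2e-4, t1 + 2e-4, by = 1e-4 * pi / 180)
  s2 <- vapply(fine, eval_theta, numeric(1))
  theta <- fine[which.min(s2)]
  ct <- cos(theta); st <- sin(theta)
  tls4d::transform2d(cr[1] - (ct * cs[1] - st * cs[2]),
                     cr[2] - (st * cs[1] + ct * cs[2]), theta)
}

make_pairs <- function(ref, src) {
  structure(list(k = nrow(ref), ref = ref, src = src),
            class = "matched_pairs")
}

# a small terrain-like irregular surface cloud for ICP tests
surface_cloud <- function(n = 3000, seed = 1) {
  set.seed(seed)
  x <- runif(n, 0, 20)
  y <- runif(n, 0, 8)
  point_cloud(x, y, 0.1 * sin(x / 3) + 0.08 * cos(y / 2))
}

tiny_layout <- function() field_layout(n_rows = 2, plots_per_row = 3)

tiny_panel <- function() cotton_genotypes()[c(1, 6, 11), ]

expect_cloud_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$x - b$x), abs(a$y - b$y), abs(a$z - b$z), 0), tol)
}
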