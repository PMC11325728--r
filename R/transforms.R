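#' Rigid SE(3) transform
#'
#' Session-level alignment currency: a proper rotation plus a translation,
#' applied as `p' = R p + t`.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation Length-3 numeric vector (meters).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be a proper orthonormal matrix")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(signif(x$translation, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic roll-pitch-yaw (x, then y, then z) composition, angles in radians.
#'
#' @param roll,pitch,yaw Rotation angles about the x, y and z axes (radians).
#' @export
rotation_euler <- function(roll = 0, pitch = 0, yaw = 0) {
  cx <- cos(roll); sx <- sin(roll)
  cy <- cos(pitch); sy <- sin(pitch)
  cz <- cos(yaw); sz <- sin(yaw)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Apply a transform to a point cloud
#'
#' @param cloud A point cloud.
#' @param tf A `rigid_transform` (or `transform2d`, which acts on x/y only).
#' @return The transformed cloud; attribute columns are preserved.
#' @export
apply_transform <- function(cloud, tf) {
  if (inherits(tf, "transform2d")) tf <- lift_transform2d(tf)
  stopifnot(inherits(tf, "rigid_transform"))
  m <- cloud_matrix(cloud) %*% t(tf$rotation)
  cloud$x <- m[, 1] + tf$translation[1]
  cloud$y <- m[, 2] + tf$translation[2]
  cloud$z <- m[, 3] + tf$translation[3]
  cloud
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform that applies `b` first,
#' then `a`.
#'
#' @param a,b `rigid_transform` objects (a `transform2d` is lifted first).
#' @export
compose_transforms <- function(a, b) {
  if (inherits(a, "transform2d")) a <- lift_transform2d(a)
  if (inherits(b, "transform2d")) b <- lift_transform2d(b)
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tf$translation))
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param tf A `rigid_transform`.
#' @export
transform_matrix <- function(tf) {
  m <- diag(4)
  m[1:3, 1:3] <- tf$rotation
  m[1:3, 4] <- tf$translation
  m
}

#' Rigid transform from a homogeneous 4x4 matrix
#' @param m A 4x4 matrix with last row (0, 0, 0, 1).
#' @export
transform_from_matrix <- function(m) {
  stopifnot(all(dim(m) == c(4, 4)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Random rigid perturbation
#'
#' Translation components uniform in `[-max_translation, max_translation]`
#' per axis; rotation from independent uniform roll/pitch/yaw angles bounded
#' by `max_angle_deg`. Used by the simulator for per-session perturbations.
#'
#' @param max_translation Bound on each translation component (meters).
#' @param max_angle_deg Bound on each Euler angle (degrees).
#' @export
random_rigid_transform <- function(max_translation = 0.5, max_angle_deg = 5) {
  ang <- runif(3, -max_angle_deg, max_angle_deg) * pi / 180
  rigid_transform(rotation_euler(ang[1], ang[2], ang[3]),
                  runif(3, -max_translation, max_translation))
}

#' Planar rigid transform
#'
#' The bird's-eye-view refinement currency: rotation by `theta`
#' (counter-clockwise about +Z, about the origin) followed by translation,
#' `p' = R(theta) p + (tx, ty)`.
#'
#' @param tx,ty Translation components (meters).
#' @param theta Rotation angle (radians).
#' @export
transform2d <- function(tx = 0, ty = 0, theta = 0) {
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty),
                 theta = as.numeric(theta)),
            class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d> Tx = %.4f m, Ty = %.4f m, theta = %.5f deg\n",
              x$tx, x$ty, x$theta * 180 / pi))
  invisible(x)
}

#' Apply a planar transform to 2D points
#' @param xy An M x 2 matrix of coordinates.
#' @param tf A `transform2d`.
#' @export
apply_transform2d <- function(xy, tf) {
  stopifnot(inherits(tf, "transform2d"))
  xy <- as.matrix(xy)
  ct <- cos(tf$theta); st <- sin(tf$theta)
  cbind(ct * xy[, 1] - st * xy[, 2] + tf$tx,
        st * xy[, 1] + ct * xy[, 2] + tf$ty)
}

#' Compose two planar transforms
#'
#' `compose_transform2d(a, b)` applies `b` first, then `a`.
#'
#' @param a,b `transform2d` objects.
#' @export
compose_transform2d <- function(a, b) {
  ct <- cos(a$theta); st <- sin(a$theta)
  transform2d(ct * b$tx - st * b$ty + a$tx,
              st * b$tx + ct * b$ty + a$ty,
              a$theta + b$theta)
}

#' Invert a planar transform
#' @param tf A `transform2d`.
#' @export
invert_transform2d <- function(tf) {
  ct <- cos(tf$theta); st <- sin(tf$theta)
  transform2d(-(ct * tf$tx + st * tf$ty), -(-st * tf$tx + ct * tf$ty), -tf$theta)
}

#' Lift a planar transform to SE(3)
#'
#' Rotation about +Z through the origin and zero Z-translation; vertical
#' alignment is owned by the terrain phase and the global renormalization.
#'
#' @param tf A `transform2d`.
#' @export
lift_transform2d <- function(tf) {
  ct <- cos(tf$theta); st <- sin(tf$theta)
  rigid_transform(matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3),
                  c(tf$tx, tf$ty, 0))
}
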