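#' Rigid-body transforms
#'
#' A `RigidTransform` is a proper rotation plus a translation, the currency of
#' all superposition and model-building steps in this package. Applying it to
#' coordinates `x` (an n x 3 matrix, Angstrom) gives `x %*% t(R) + t`.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 translation vector, Angstrom.
#' @return An object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (tolerance 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix must be proper (det +1); got det = ", det(rotation))
  structure(list(rotation = rotation, translation = translation),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  ra <- rotation_angle(x)
  cat(sprintf("RigidTransform: rotation %.3f deg about (%.3f, %.3f, %.3f), |t| = %.3f A\n",
              ra$angle_deg, ra$axis[1], ra$axis[2], ra$axis[3],
              sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A [rigid_transform()].
#' @param xyz n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates, same shape as input.
#' @export
apply_transform <- function(transform, xyz) {
  stopifnot(inherits(transform, "RigidTransform"))
  vec <- is.null(dim(xyz))
  xyz <- matrix(xyz, ncol = 3)
  out <- xyz %*% t(transform$rotation) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
  if (vec) out <- drop(out)
  out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` is the transform "first a, then b".
#' @param b,a [rigid_transform()] objects.
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  drop(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -drop(rt %*% transform$translation))
}

#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle_deg rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid rotation about an axis through a point
#'
#' Convenience wrapper returning a full [rigid_transform()] that rotates by
#' `angle_deg` about the line through `point` with direction `axis`.
#' @inheritParams rotation_about_axis
#' @param point length-3 point on the rotation axis, Angstrom.
#' @export
rotation_about_line <- function(axis, angle_deg, point = c(0, 0, 0)) {
  R <- rotation_about_axis(axis, angle_deg)
  rigid_transform(R, as.numeric(point) - drop(R %*% as.numeric(point)))
}

#' Rotation angle and axis of a rigid transform
#'
#' The angle is `acos((trace(R) - 1)/2)` in `[0, 180]` degrees; the axis is the
#' rotation eigenvector with its sign chosen so the angle is positive
#' (right-handed). For the identity the angle is 0 and the axis is reported as
#' (0, 0, 1) by convention.
#'
#' @param transform A [rigid_transform()] or bare 3x3 rotation matrix.
#' @return List with `angle_deg` and unit `axis`.
#' @export
rotation_angle <- function(transform) {
  R <- if (inherits(transform, "RigidTransform")) transform$rotation else transform
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  angle <- acos(ct) * 180 / pi
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(v^2))
  if (s > 1e-9) {
    axis <- v / s
  } else if (angle < 90) {            # identity-like
    axis <- c(0, 0, 1)
  } else {                            # 180-degree rotation: axis from R + I
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    axis <- M[, j] / sqrt(sum(M[, j]^2))
  }
  list(angle_deg = angle, axis = axis)
}

#' A uniformly random rotation matrix
#'
#' Used by the synthetic-data module to draw unbiased rigid perturbations.
#' Draws a quaternion from an isotropic Gaussian and normalizes it.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Fractional power of a rotation: rotate by s * angle about the same axis.
partial_rotation <- function(R, s) {
  ra <- rotation_angle(R)
  rotation_about_axis(ra$axis, s * ra$angle_deg)
}
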