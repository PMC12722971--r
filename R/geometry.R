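# Rigid 3D geometry: unit quaternions and rigid (rotation + translation)
# transforms.  All coordinates are millimetres in a right-handed frame with
# DICOM patient axes: x medio-lateral (+left), y anterior-posterior
# (+posterior), z inferior-superior (+superior).

#' Construct a unit quaternion
#'
#' Quaternions are stored as numeric vectors `c(w, x, y, z)` (scalar first)
#' and canonicalized so that `w >= 0` (the double cover `q` / `-q` maps to a
#' single representative; both describe the same rotation).
#'
#' @param w,x,y,z Quaternion components.
#' @param normalize Normalize to unit length (default `TRUE`).
#' @return A numeric vector of length 4 with class `"quaternion"`.
#' @export
quaternion <- function(w = 1, x = 0, y = 0, z = 0, normalize = TRUE) {
  q <- unname(c(w, x, y, z))
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero-norm quaternion")
  if (normalize) q <- q / n
  structure(quat_canonical(q), class = "quaternion")
}

quat_canonical <- function(q) {
  # pick the representative with w >= 0; for w == 0, first nonzero > 0
  nz <- which(abs(q) > 1e-15)
  if (length(nz) && q[nz[1]] < 0) q <- -q
  q
}

quat_norm <- function(q) sqrt(sum(q^2))

#' @rdname quaternion
#' @param axis Rotation axis (length-3, need not be normalized).
#' @param angle Rotation angle in radians (right-handed about `axis`).
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  quaternion(cos(angle / 2), sin(angle / 2) * axis[1],
             sin(angle / 2) * axis[2], sin(angle / 2) * axis[3])
}

quat_multiply <- function(a, b) {
  w <- a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4]
  x <- a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3]
  y <- a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2]
  z <- a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  structure(quat_canonical(c(w, x, y, z)), class = "quaternion")
}

quat_conjugate <- function(q) {
  structure(quat_canonical(c(q[1], -q[2], -q[3], -q[4])), class = "quaternion")
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' @param q A `quaternion`.
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Uses the numerically stable branch selection on the matrix trace.
#'
#' @param m A 3x3 proper rotation matrix.
#' @return A `quaternion`.
#' @export
matrix_to_quat <- function(m) {
  tr <- m[1, 1] + m[2, 2] + m[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s)
  } else if (m[1, 1] > m[2, 2] && m[1, 1] > m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, 0.25 * s, (m[1, 2] + m[2, 1]) / s,
           (m[1, 3] + m[3, 1]) / s)
  } else if (m[2, 2] > m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s, 0.25 * s,
           (m[2, 3] + m[3, 2]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s,
           (m[2, 3] + m[3, 2]) / s, 0.25 * s)
  }
  quaternion(q[1], q[2], q[3], q[4])
}

#' Construct a rigid transform
#'
#' A rigid transform maps points `p` to `R p + t` where `R` is the rotation
#' encoded by the unit quaternion `q` and `t` is a translation in mm.
#'
#' @param q Rotation as a `quaternion` (default identity).
#' @param t Translation, numeric length 3, mm.
#' @return An object of class `"rigid_transform"`.
#' @export
rigid <- function(q = quaternion(), t = c(0, 0, 0)) {
  if (!inherits(q, "quaternion")) q <- do.call(quaternion, as.list(q))
  t <- as.numeric(t)
  if (length(t) != 3 || !all(is.finite(t)))
    stop("translation must be 3 finite numbers (mm)")
  structure(list(q = q, t = t), class = "rigid_transform")
}

#' @rdname rigid
#' @export
rigid_identity <- function() rigid()

#' Compose two rigid transforms
#'
#' `rigid_compose(a, b)` maps `p` to `a(b(p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rigid_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  Ra <- quat_to_matrix(a$q)
  rigid(quat_multiply(a$q, b$q), as.numeric(Ra %*% b$t) + a$t)
}

#' Invert a rigid transform
#'
#' @param tr A `rigid_transform`.
#' @return The inverse transform, so `rigid_compose(rigid_invert(tr), tr)`
#'   is the identity to machine precision.
#' @export
rigid_invert <- function(tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  qi <- quat_conjugate(tr$q)
  rigid(qi, as.numeric(-(quat_to_matrix(qi) %*% tr$t)))
}

#' Apply a rigid transform to points
#'
#' @param tr A `rigid_transform`.
#' @param p A length-3 numeric point or an n x 3 matrix of points (mm).
#' @return Transformed points in the same shape as the input.
#' @export
rigid_apply <- function(tr, p) {
  stopifnot(inherits(tr, "rigid_transform"))
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, ncol = 3) else as.matrix(p)
  if (ncol(m) != 3) stop("points must have 3 columns (x, y, z)")
  if (!all(is.finite(m))) stop("non-finite point coordinates")
  out <- m %*% t(quat_to_matrix(tr$q))
  out <- sweep(out, 2, tr$t, "+")
  if (vec) as.numeric(out) else {
    colnames(out) <- c("x", "y", "z")
    out
  }
}

#' Convert between rigid transforms and homogeneous matrices
#'
#' `rigid_to_matrix4` returns the 4x4 homogeneous matrix; `rigid_from_matrix4`
#' inverts it.  `rigid_to_matrix12`/`rigid_from_matrix12` use the row-major
#' 12-number serialization (3x4: rotation rows with appended translation)
#' used in configuration and report files.
#'
#' @param tr A `rigid_transform`.
#' @param m A 4x4 homogeneous rigid matrix, or a length-12 numeric vector.
#' @return A matrix / numeric vector, or a `rigid_transform`.
#' @export
rigid_to_matrix4 <- function(tr) {
  m <- diag(4)
  m[1:3, 1:3] <- quat_to_matrix(tr$q)
  m[1:3, 4] <- tr$t
  m
}

#' @rdname rigid_to_matrix4
#' @export
rigid_from_matrix4 <- function(m) {
  R <- m[1:3, 1:3]
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("matrix block is not a proper rotation")
  rigid(matrix_to_quat(R), m[1:3, 4])
}

#' @rdname rigid_to_matrix4
#' @export
rigid_to_matrix12 <- function(tr) {
  as.numeric(t(rigid_to_matrix4(tr)[1:3, ]))
}

#' @rdname rigid_to_matrix4
#' @export
rigid_from_matrix12 <- function(m) {
  if (length(m) != 12) stop("expected 12 numbers (row-major 3x4 rigid block)")
  m4 <- rbind(matrix(m, nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  rigid_from_matrix4(m4)
}

#' Measured 6DoF reference-sensor pose
#'
#' The pose of the template-mounted reference sensor in the EMT frame:
#' `position` is the sensor origin (mm) and `orientation` the rotation taking
#' sensor-local axes into EMT axes.  Interpreted as a rigid transform it maps
#' sensor-local coordinates to EMT coordinates.
#'
#' @param position Sensor origin in the EMT frame, mm.
#' @param orientation Sensor orientation as a `quaternion`.
#' @return An object of class `"reference_pose"`.
#' @export
reference_pose <- function(position, orientation) {
  if (!inherits(orientation, "quaternion"))
    orientation <- do.call(quaternion, as.list(orientation))
  position <- as.numeric(position)
  if (length(position) != 3 || !all(is.finite(position)))
    stop("reference pose position must be 3 finite numbers")
  structure(list(position = position, orientation = orientation),
            class = "reference_pose")
}

#' @rdname reference_pose
#' @param pose A `reference_pose`.
#' @export
pose_as_transform <- function(pose) {
  stopifnot(inherits(pose, "reference_pose"))
  rigid(pose$orientation, pose$position)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform (mm)\n")
  cat("  quaternion (w x y z):", sprintf("%.6f", unclass(x$q)), "\n")
  cat("  translation:         ", sprintf("%.4f", x$t), "\n")
  invisible(x)
}

#' @export
print.reference_pose <- function(x, ...) {
  cat("6DoF reference pose (EMT frame)\n")
  cat("  position:   ", sprintf("%.4f", x$position), "\n")
  cat("  orientation:", sprintf("%.6f", unclass(x$orientation)), "\n")
  invisible(x)
}
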