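# Registration of EMT measurements to the DICOM RT-plan frame.
#
# Workflow 2: direct registration through the template-mounted 6DoF
# reference sensor -- the measured sensor pose in the EMT frame is combined
# with the known (calibrated) pose of the same sensor relative to the DICOM
# frame; no fitting is involved.
#
# Workflow 1: least-squares rigid fit (SVD / Kabsch, reflection-corrected)
# to point correspondences between EMT measurement points and an existing
# TRUS-based (pre)reconstruction.

#' Template-holder calibration
#'
#' The pose of the reference sensor relative to the DICOM coordinate system,
#' fixed by the template-holder design.
#'
#' @param ref_in_dicom A [rigid()] transform mapping sensor-local coordinates
#'   to DICOM coordinates.
#' @return An object of class `"template_calibration"`.
#' @export
template_calibration <- function(ref_in_dicom) {
  stopifnot(inherits(ref_in_dicom, "rigid_transform"))
  structure(list(ref_in_dicom = ref_in_dicom), class = "template_calibration")
}

registration_result <- function(transform, rms_residual, method) {
  structure(list(transform = transform, rms_residual = rms_residual,
                 method = method),
            class = "registration_result")
}

#' Direct registration via the 6DoF reference sensor (Workflow 2)
#'
#' The EMT-to-DICOM transform is `ref_in_dicom o inverse(pose)`: a point
#' expressed in EMT coordinates is first carried into sensor-local
#' coordinates through the inverse of the measured pose, then into DICOM
#' coordinates through the calibration.  Exact (no fitting step).
#'
#' @param pose The measured [reference_pose()] in the EMT frame.
#' @param calib The [template_calibration()].
#' @return A `"registration_result"` with `method = "reference_sensor"` and
#'   `rms_residual = 0`.
#' @export
register_reference_sensor <- function(pose, calib) {
  stopifnot(inherits(pose, "reference_pose"),
            inherits(calib, "template_calibration"))
  n <- quat_norm(unclass(pose$orientation))
  if (abs(n - 1) > 1e-6)
    stop(sprintf("degenerate reference pose: orientation norm %.3g != 1", n))
  tr <- rigid_compose(calib$ref_in_dicom,
                      rigid_invert(pose_as_transform(pose)))
  registration_result(tr, 0, "reference_sensor")
}

#' Least-squares rigid registration from point correspondences (Workflow 1)
#'
#' Finds the rigid transform T minimizing sum |T(emt_i) - dicom_i|^2 by the
#' closed-form SVD solution on centered coordinates; a reflection-optimal
#' solution is corrected to a proper rotation (det +1).
#'
#' @param emt_points n x 3 matrix of points in the EMT frame (mm), or a data
#'   frame with columns `ex ey ez dx dy dz` holding both point sets.
#' @param dicom_points n x 3 matrix of corresponding DICOM-frame points.
#' @return A `"registration_result"` with `method = "point_correspondence"`
#'   and `rms_residual` the root-mean-square post-fit pair distance (mm).
#' @export
register_point_correspondence <- function(emt_points, dicom_points = NULL) {
  if (is.null(dicom_points)) {
    df <- as.data.frame(emt_points)
    emt_points <- as.matrix(df[, c("ex", "ey", "ez")])
    dicom_points <- as.matrix(df[, c("dx", "dy", "dz")])
  }
  A <- as.matrix(emt_points); B <- as.matrix(dicom_points)
  if (nrow(A) != nrow(B)) stop("correspondence point counts differ")
  if (nrow(A) < 3) stop("need >= 3 correspondence pairs, got ", nrow(A))
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: the centered EMT set must span a plane
  sv <- svd(A0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate correspondence set: points are collinear")
  s <- svd(crossprod(A0, B0))       # H = A0' B0 ;  R = V diag(1,1,d) U'
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rigid(matrix_to_quat(R), cb - as.numeric(R %*% ca))
  res <- rigid_apply(tr, A) - B
  registration_result(tr, sqrt(mean(rowSums(res^2))), "point_correspondence")
}

#' Map measurement series into the DICOM frame
#'
#' @param series A list of [measurement_series()] (or a single one).
#' @param reg A `"registration_result"`.
#' @return The series with every point mapped by `reg$transform`; ordering,
#'   channel ids and flags preserved.
#' @export
transform_series <- function(series, reg) {
  stopifnot(inherits(reg, "registration_result"))
  one <- inherits(series, "measurement_series")
  if (one) series <- list(series)
  out <- lapply(series, function(s) {
    s$points <- rigid_apply(reg$transform, s$points)
    s
  })
  if (one) out[[1]] else out
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration (%s): rms residual %.4f mm\n",
              x$method, x$rms_residual))
  print(x$transform)
  invisible(x)
}
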