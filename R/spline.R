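# Needle path reconstruction: interpolating cubic splines through the
# registered measurement points, parameterized by cumulative chord length,
# with arc-length resampling for control points and dwell positions.
# End conditions are the classic cubic-extrapolation (Forsythe-Malcolm-
# Moler) kind: they reproduce low-order polynomial paths -- in particular
# the gentle quadratic bows real needles exhibit -- exactly, where natural
# (zero second derivative) ends flatten the curvature in the end segments
# and bias the tip-side arc length.
#
# The dwell grid is anchored at the distal tip (arc offset 0 = tip), matching
# the measurement protocol which starts at the most distal dwell position;
# a template-anchored grid is available through `tip_offset`.

#' Fit an interpolating cubic spline through a measurement series
#'
#' An interpolating cubic spline (Forsythe-Malcolm-Moler end conditions:
#' cubic extrapolation through the outermost four points) is fitted per
#' coordinate against the cumulative chord-length parameter.  With exactly
#' two points the path is the straight segment.  Arc length is computed by
#' adaptive numerical quadrature of the parametric speed.
#'
#' @param series A [measurement_series()], or an n x 3 point matrix
#'   (distal point first).
#' @param channel_id Channel id when `series` is a bare matrix.
#' @return An object of class `"needle_spline"` with fields `channel_id`,
#'   `points`, knot parameters `u`, per-coordinate spline functions, knot
#'   cumulative arc lengths `cum_arc` and `total_arc_length` (mm).
#' @export
fit_needle_spline <- function(series, channel_id = NULL) {
  if (inherits(series, "measurement_series")) {
    pts <- series$points
    if (is.null(channel_id)) channel_id <- series$channel_id
  } else {
    pts <- as.matrix(series)
    if (is.null(channel_id)) channel_id <- NA_integer_
  }
  n <- nrow(pts)
  if (n < 2) stop("need >= 2 points to fit a needle path")
  chords <- sqrt(rowSums(diff(pts)^2))
  if (any(chords < 1e-9))
    stop("duplicate consecutive measurement points (zero chord)")
  u <- c(0, cumsum(chords))
  fx <- stats::splinefun(u, pts[, 1], method = "fmm")
  fy <- stats::splinefun(u, pts[, 2], method = "fmm")
  fz <- stats::splinefun(u, pts[, 3], method = "fmm")
  speed <- function(t) sqrt(fx(t, deriv = 1)^2 + fy(t, deriv = 1)^2 +
                              fz(t, deriv = 1)^2)
  seg_arc <- vapply(seq_len(n - 1), function(i)
    stats::integrate(speed, u[i], u[i + 1], rel.tol = 1e-10,
                     abs.tol = 1e-10)$value, numeric(1))
  cum_arc <- c(0, cumsum(seg_arc))
  sp <- structure(list(channel_id = as.integer(channel_id), points = pts,
                       u = u, fx = fx, fy = fy, fz = fz, speed = speed,
                       cum_arc = cum_arc,
                       total_arc_length = cum_arc[n]),
                  class = "needle_spline")
  sp
}

#' Evaluate a needle spline
#'
#' @param spline A `"needle_spline"`.
#' @param t Chord-length parameter values (knot parameterization).
#' @return An m x 3 matrix of points.
#' @export
spline_eval <- function(spline, t) {
  cbind(x = spline$fx(t), y = spline$fy(t), z = spline$fz(t))
}

# arc length from the distal tip (parameter 0) to parameter t
spline_arc_at <- function(spline, t) {
  i <- findInterval(t, spline$u, rightmost.closed = TRUE)
  i <- pmax(1L, pmin(i, length(spline$u) - 1L))
  vapply(seq_along(t), function(k) {
    spline$cum_arc[i[k]] +
      stats::integrate(spline$speed, spline$u[i[k]], t[k],
                       rel.tol = 1e-10, abs.tol = 1e-10)$value
  }, numeric(1))
}

# invert arc length: parameter t with arc(t) = s, by bisection/uniroot
spline_param_at_arc <- function(spline, s) {
  vapply(s, function(si) {
    if (si <= 0) return(spline$u[1])
    if (si >= spline$total_arc_length) return(spline$u[length(spline$u)])
    i <- findInterval(si, spline$cum_arc, rightmost.closed = TRUE)
    stats::uniroot(function(t) spline_arc_at(spline, t) - si,
                   lower = spline$u[i], upper = spline$u[i + 1],
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Points at given arc lengths from the distal tip
#'
#' @param spline A `"needle_spline"`.
#' @param s Arc lengths from the tip, mm.
#' @return An m x 3 matrix of points on the spline.
#' @export
spline_point_at_arc <- function(spline, s) {
  spline_eval(spline, spline_param_at_arc(spline, s))
}

#' Resample control points at fixed arc spacing
#'
#' Control points are placed at arc lengths 0, `spacing`, 2 `spacing`, ...
#' from the distal tip, plus the exact proximal end.  When `spacing` is not
#' smaller than the path length only the two endpoints are returned.
#'
#' @param spline A `"needle_spline"`.
#' @param spacing Arc spacing, mm (> 0).
#' @return An m x 3 matrix of control points, distal tip first.
#' @export
resample_control_points <- function(spline, spacing = 5) {
  if (spacing <= 0) stop("control-point spacing must be > 0")
  L <- spline$total_arc_length
  s <- seq(0, L, by = spacing)
  if (L - s[length(s)] > 1e-9) s <- c(s, L) else s[length(s)] <- L
  if (length(s) < 2) s <- c(0, L)
  spline_point_at_arc(spline, s)
}

#' A set of dwell positions on a reconstructed needle
#'
#' @param channel_id Channel id.
#' @param positions n x 3 matrix, distal dwell first.
#' @param arc_offsets Arc lengths from the distal tip, mm.
#' @param step Dwell step, mm.
#' @return An object of class `"dwell_set"`.
#' @export
dwell_set <- function(channel_id, positions, arc_offsets, step) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y", "z")
  structure(list(channel_id = as.integer(channel_id), positions = positions,
                 arc_offsets = arc_offsets, step = step),
            class = "dwell_set")
}

#' Derive dwell positions along the spline
#'
#' Dwell k (k = 0, 1, ...) sits at arc length `tip_offset + k * step` from
#' the distal tip.  With `n_dwells = NULL` the count is the largest number
#' of dwells that fit on the path.
#'
#' @param spline A `"needle_spline"`.
#' @param step Dwell step, mm (> 0).
#' @param tip_offset Arc offset of the first (most distal) dwell from the
#'   tip, mm (>= 0).
#' @param n_dwells Number of dwells, or `NULL` for automatic truncation at
#'   the proximal end.
#' @return A [dwell_set()].
#' @export
derive_dwells <- function(spline, step = 5, tip_offset = 0, n_dwells = NULL) {
  if (step <= 0) stop("dwell step must be > 0")
  if (tip_offset < 0) stop("tip_offset must be >= 0")
  L <- spline$total_arc_length
  if (tip_offset > L + 1e-9)
    stop(sprintf("tip_offset %.2f mm beyond path length %.2f mm",
                 tip_offset, L))
  # with an explicit count, tolerate the measured path falling slightly
  # short of the nominal grid (noise): clamp the proximal dwell to the end
  slack <- if (is.null(n_dwells)) 1e-4 else step / 2
  if (is.null(n_dwells))
    n_dwells <- floor((L - tip_offset) / step + 1e-6) + 1
  s <- tip_offset + step * (seq_len(n_dwells) - 1)
  if (s[n_dwells] > L + slack)
    stop("requested dwells extend beyond the needle path")
  s <- pmin(s, L)
  dwell_set(spline$channel_id, spline_point_at_arc(spline, s),
            arc_offsets = tip_offset + step * (seq_len(n_dwells) - 1),
            step = step)
}

#' Free needle length beyond the template plane
#'
#' Arc length from the point where the needle path crosses the template
#' plane (z = `template_plane_z`) to the proximal end.  Used only as a
#' verification quantity.
#'
#' @param spline A `"needle_spline"`.
#' @param template_plane_z Template plane z coordinate, mm.
#' @return Free length, mm.
#' @export
free_length <- function(spline, template_plane_z) {
  u <- spline$u
  g <- function(t) spline$fz(t) - template_plane_z
  vals <- g(u)
  i <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(i)) {
    # search inside segments too (curved paths may dip through the plane)
    stop("needle path does not cross the template plane at z = ",
         template_plane_z)
  }
  i <- i[length(i)]  # proximal-most crossing
  t0 <- if (abs(vals[i]) < 1e-14) u[i] else if (abs(vals[i + 1]) < 1e-14)
    u[i + 1] else
      stats::uniroot(g, lower = u[i], upper = u[i + 1], tol = 1e-12)$root
  spline$total_arc_length - spline_arc_at(spline, t0)
}

#' A fully reconstructed needle
#'
#' Fits the spline, resamples control points, derives dwells and (optionally)
#' the free length in one call.
#'
#' @param series A [measurement_series()] in the DICOM frame.
#' @param control_spacing Control-point arc spacing, mm.
#' @param step Dwell step, mm.
#' @param tip_offset Distal offset of the dwell grid, mm.
#' @param n_dwells Dwell count or `NULL` (auto).
#' @param template_plane_z Template plane z for the free-length check, or
#'   `NULL` to skip.
#' @return An object of class `"reconstructed_needle"` with fields
#'   `channel_id`, `spline`, `control_points`, `dwells`, `free_length`.
#' @export
reconstruct_needle <- function(series, control_spacing = 5, step = 5,
                               tip_offset = 0, n_dwells = NULL,
                               template_plane_z = NULL) {
  sp <- fit_needle_spline(series)
  fl <- if (is.null(template_plane_z)) NA_real_ else
    free_length(sp, template_plane_z)
  structure(list(channel_id = sp$channel_id, spline = sp,
                 control_points = resample_control_points(sp, control_spacing),
                 dwells = derive_dwells(sp, step, tip_offset, n_dwells),
                 free_length = fl),
            class = "reconstructed_needle")
}

#' Reconstruct all needles of an implant
#'
#' @param series_list List of [measurement_series()] in the DICOM frame.
#' @param ... Passed to [reconstruct_needle()].
#' @return A list of `"reconstructed_needle"` objects, channel ascending.
#' @export
reconstruct_implant <- function(series_list, ...) {
  ord <- order(vapply(series_list, `[[`, integer(1), "channel_id"))
  lapply(series_list[ord], reconstruct_needle, ...)
}

#' Write / read the reconstruction exchange TSV
#'
#' Format: `channel point_index x y z kind` with `kind` one of `control`,
#' `dwell`; point indices are 0-based, distal first.
#'
#' @param needles List of `"reconstructed_needle"` objects.
#' @param path Output TSV path.
#' @return `write_reconstruction_tsv` returns `path` invisibly;
#'   `read_reconstruction_tsv` returns a data frame.
#' @export
write_reconstruction_tsv <- function(needles, path) {
  rows <- do.call(rbind, lapply(needles, function(nd) {
    rbind(
      data.frame(channel = nd$channel_id,
                 point_index = seq_len(nrow(nd$control_points)) - 1L,
                 x = nd$control_points[, 1], y = nd$control_points[, 2],
                 z = nd$control_points[, 3], kind = "control"),
      data.frame(channel = nd$channel_id,
                 point_index = seq_len(nrow(nd$dwells$positions)) - 1L,
                 x = nd$dwells$positions[, 1], y = nd$dwells$positions[, 2],
                 z = nd$dwells$positions[, 3], kind = "dwell"))
  }))
  utils::write.table(format(rows, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reconstruction_tsv
#' @export
read_reconstruction_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @export
print.reconstructed_needle <- function(x, ...) {
  cat(sprintf(
    "reconstructed needle: channel %d, arc %.2f mm, %d control pts, %d dwells%s\n",
    x$channel_id, x$spline$total_arc_length, nrow(x$control_points),
    nrow(x$dwells$positions),
    if (is.finite(x$free_length))
      sprintf(", free length %.1f mm", x$free_length) else ""))
  invisible(x)
}
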