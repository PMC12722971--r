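# Step-and-shoot EMT acquisition: raw sample parsing and robust aggregation
# into per-needle measurement series.
#
# Raw file format (UTF-8 TSV, '#' comments):
#   channel step x y z [qw qx qy qz rx ry rz] [quality]
# Positions are mm in the EMT frame; step 0 is the most distal position
# (needle tip); the optional 9 pose/quality columns carry the 6DoF
# reference-sensor pose measured alongside each sample and a vendor quality
# indicator in [0, 1].

#' Acquisition configuration
#'
#' Parameters of the step-and-shoot protocol and of raw-sample aggregation.
#' The defaults mirror the phantom protocol: 11 positions spaced 5 mm apart
#' (covering 50 mm per needle).
#'
#' @param step_spacing Nominal sensor step, mm.
#' @param n_steps Number of step-and-shoot positions per needle.
#' @param outlier_mad_threshold Reject a sample when its distance to the
#'   per-(channel, step) coordinate-wise median exceeds this multiple of the
#'   MAD of those distances (taken about zero, since the distances are
#'   already deviations; strict exceedance, ties are kept).
#' @param min_samples_per_point Minimum surviving samples per measurement
#'   point after rejection.
#' @param quality_min Samples with a quality value strictly below this are
#'   dropped before aggregation; samples without a quality value are kept.
#' @return A list of class `"acquisition_config"`.
#' @export
acquisition_config <- function(step_spacing = 5, n_steps = 11,
                               outlier_mad_threshold = 3.5,
                               min_samples_per_point = 3,
                               quality_min = 0.5) {
  if (step_spacing <= 0) stop("step_spacing must be > 0")
  if (n_steps < 2) stop("n_steps must be >= 2")
  structure(list(step_spacing = step_spacing, n_steps = n_steps,
                 outlier_mad_threshold = outlier_mad_threshold,
                 min_samples_per_point = min_samples_per_point,
                 quality_min = quality_min),
            class = "acquisition_config")
}

#' Parse a raw step-and-shoot EMT sample file
#'
#' @param path Path to a raw EMT TSV file (see format above).
#' @return A list of class `"emt_raw"` with elements `samples` (data frame:
#'   `channel`, `step`, `x`, `y`, `z`, optional `qw qx qy qz rx ry rz`,
#'   optional `quality`, and the source `line` number), `n_rejected`,
#'   `rejected_lines`, and `has_reference_pose`.
#' @export
parse_emt_raw <- function(path) {
  if (!file.exists(path)) stop("raw EMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no samples: file '", basename(path), "' is empty")
  header <- strsplit(trimws(lines[idx[1]]), "\t")[[1]]
  body_idx <- idx[-1]
  req <- c("channel", "step", "x", "y", "z")
  if (!all(req %in% header))
    stop("missing required columns: ",
         paste(setdiff(req, header), collapse = ", "))
  pose_cols <- c("qw", "qx", "qy", "qz", "rx", "ry", "rz")
  has_pose <- all(pose_cols %in% header)
  if (any(pose_cols %in% header) && !has_pose)
    stop("reference-pose columns must be all present or all absent")
  has_quality <- "quality" %in% header
  if (!length(body_idx)) stop("no samples: file has a header but no rows")

  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == length(header)
  num <- matrix(NA_real_, nrow = length(fields), ncol = length(header),
                dimnames = list(NULL, header))
  if (any(ncol_ok)) {
    m <- do.call(rbind, fields[ncol_ok])
    suppressWarnings(storage <- matrix(as.numeric(m), nrow = sum(ncol_ok)))
    num[ncol_ok, ] <- storage
  }
  need <- c(req, if (has_pose) pose_cols)
  row_ok <- ncol_ok & apply(num[, need, drop = FALSE], 1, function(v)
    all(is.finite(v)))
  # channel/step must be non-negative integers, channel >= 1
  row_ok <- row_ok &
    !is.na(num[, "channel"]) & num[, "channel"] >= 1 &
    num[, "channel"] == round(num[, "channel"]) &
    !is.na(num[, "step"]) & num[, "step"] >= 0 &
    num[, "step"] == round(num[, "step"])
  bad_lines <- body_idx[!row_ok]
  if (!any(row_ok)) stop("no samples: all ", length(fields), " rows malformed")
  frac_bad <- length(bad_lines) / length(fields)
  if (frac_bad > 0.10)
    stop(sprintf("%.0f%% of rows malformed (> 10%%) in '%s'",
                 100 * frac_bad, basename(path)))
  if (length(bad_lines))
    warning(length(bad_lines), " malformed row(s) skipped (lines ",
            paste(utils::head(bad_lines, 5), collapse = ", "),
            if (length(bad_lines) > 5) ", ..." else "", ")")
  df <- as.data.frame(num[row_ok, need, drop = FALSE])
  if (has_quality) df$quality <- num[row_ok, "quality"]
  df$line <- body_idx[row_ok]
  structure(list(samples = df, n_rejected = length(bad_lines),
                 rejected_lines = bad_lines, has_reference_pose = has_pose),
            class = "emt_raw")
}

#' A per-needle ordered measurement series
#'
#' @param channel_id Afterloader channel number.
#' @param points n x 3 matrix of measurement points, mm; row 1 is the most
#'   distal point (needle tip side).
#' @param step_spacing Nominal step, mm.
#' @param n_samples_per_point Typical raw-sample count per point.
#' @param flags Character vector of quality flags (e.g. chord-length
#'   warnings); empty when clean.
#' @return An object of class `"measurement_series"`.
#' @export
measurement_series <- function(channel_id, points, step_spacing,
                               n_samples_per_point = 1L,
                               flags = character()) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a measurement series needs >= 2 points")
  if (!all(is.finite(points))) stop("non-finite measurement point")
  colnames(points) <- c("x", "y", "z")
  structure(list(channel_id = as.integer(channel_id), points = points,
                 step_spacing = step_spacing,
                 n_samples_per_point = as.integer(n_samples_per_point),
                 flags = flags),
            class = "measurement_series")
}

robust_center <- function(pts, mad_threshold) {
  med <- apply(pts, 2, stats::median)
  d <- sqrt(rowSums(sweep(pts, 2, med)^2))
  # the distances are already deviations from the robust center, so the
  # MAD is taken about zero; this stays stable down to a handful of samples
  s <- stats::mad(d, center = 0)
  keep <- if (s > 0) d <= mad_threshold * s else d <= 0
  if (!any(keep)) keep <- rep(TRUE, nrow(pts))  # degenerate: keep all
  list(center = apply(pts[keep, , drop = FALSE], 2, stats::median),
       n_kept = sum(keep))
}

#' Aggregate raw samples into per-needle measurement series
#'
#' Samples are grouped by (channel, step); each group is reduced to a robust
#' center: the coordinate-wise median after rejecting samples whose distance
#' to the group median strictly exceeds `outlier_mad_threshold` times the MAD
#' of those distances.  Series are ordered distal-first (step ascending) and
#' channels ascending.  Consecutive points whose chord length falls outside
#' [0.5, 1.5] x `step_spacing` raise a warning flag on the series.
#'
#' @param raw An `"emt_raw"` object from [parse_emt_raw()], or a data frame
#'   with columns `channel`, `step`, `x`, `y`, `z` (optional `quality`).
#' @param cfg An [acquisition_config()].
#' @return A list of [measurement_series()], one per channel, sorted by
#'   channel id.
#' @export
aggregate_series <- function(raw, cfg = acquisition_config()) {
  df <- if (inherits(raw, "emt_raw")) raw$samples else as.data.frame(raw)
  if (!nrow(df)) stop("no samples to aggregate")
  groups_before <- unique(df[, c("channel", "step")])
  if (!is.null(df$quality)) {
    gated <- !is.na(df$quality) & df$quality < cfg$quality_min
    df <- df[!gated, , drop = FALSE]
    if (!nrow(df)) stop("all samples below quality threshold")
    lost <- !paste(groups_before$channel, groups_before$step) %in%
      paste(df$channel, df$step)
    if (any(lost))
      stop("channel ", groups_before$channel[lost][1], " step ",
           groups_before$step[lost][1],
           ": no samples survive the quality gate")
  }
  out <- list()
  for (ch in sort(unique(df$channel))) {
    sub <- df[df$channel == ch, , drop = FALSE]
    steps <- sort(unique(sub$step))
    pts <- matrix(NA_real_, nrow = length(steps), ncol = 3)
    n_kept <- integer(length(steps))
    for (i in seq_along(steps)) {
      grp <- as.matrix(sub[sub$step == steps[i], c("x", "y", "z")])
      rc <- robust_center(grp, cfg$outlier_mad_threshold)
      if (rc$n_kept < cfg$min_samples_per_point)
        stop(sprintf(
          "channel %d step %d: only %d sample(s) survive outlier rejection (need >= %d)",
          ch, steps[i], rc$n_kept, cfg$min_samples_per_point))
      pts[i, ] <- rc$center
      n_kept[i] <- rc$n_kept
    }
    flags <- character()
    chords <- sqrt(rowSums(diff(pts)^2))
    off <- chords < 0.5 * cfg$step_spacing | chords > 1.5 * cfg$step_spacing
    if (any(off)) {
      flags <- sprintf("chord length %.2f mm at step %d outside [%.2f, %.2f]",
                       chords[off], steps[which(off)],
                       0.5 * cfg$step_spacing, 1.5 * cfg$step_spacing)
      warning("channel ", ch, ": ", length(flags), " chord-length anomaly(ies)")
    }
    out[[length(out) + 1L]] <- measurement_series(
      ch, pts, cfg$step_spacing,
      n_samples_per_point = as.integer(stats::median(n_kept)), flags = flags)
  }
  out
}

#' Extract the averaged reference pose from a raw EMT file
#'
#' When each sample row carries a measured reference-sensor pose, the
#' session pose is the average: translation by the coordinate-wise mean and
#' rotation by the chordal mean of the canonicalized quaternions
#' (renormalized).
#'
#' @param raw An `"emt_raw"` object with reference-pose columns.
#' @return A [reference_pose()].
#' @export
session_reference_pose <- function(raw) {
  stopifnot(inherits(raw, "emt_raw"))
  if (!raw$has_reference_pose)
    stop("raw file carries no reference-pose columns")
  df <- raw$samples
  qs <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  qs <- t(apply(qs, 1, function(q) quat_canonical(q / sqrt(sum(q^2)))))
  qm <- colMeans(qs)
  reference_pose(colMeans(as.matrix(df[, c("rx", "ry", "rz")])),
                 quaternion(qm[1], qm[2], qm[3], qm[4]))
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("measurement series: channel %d, %d points, step %.1f mm%s\n",
              x$channel_id, nrow(x$points), x$step_spacing,
              if (length(x$flags)) paste0(" [", length(x$flags), " flag(s)]")
              else ""))
  invisible(x)
}
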