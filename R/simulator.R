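# Synthetic phantom: template-grid multi-needle implants with mild
# curvature, step-and-shoot EMT sessions with a 6DoF reference pose, TRUS
# observer reconstructions with injectable gross errors, and anatomy /
# clinical-style plan generation.  This module replaces the tracking
# hardware and patient data; every output is deterministic per seed
# (R's default Mersenne-Twister stream, one `set.seed()` per operation).
#
# Geometry: the template plane is z = 0; needles are inserted along +z
# (superior), tips distal at z ~ 55 mm, with a quadratic lateral bow that
# vanishes at the proximal end and peaks at the tip.  Dwells sit at 5 mm
# arc spacing starting at the tip (most distal dwell), matching the
# step-and-shoot protocol of 11 positions over 50 mm.

#' Phantom implant specification
#'
#' @param n_needles Number of implanted needles.
#' @param grid_pitch Template hole pitch, mm (13 x 13 hole array).
#' @param needle_length Covered measurement length, mm (dwells span
#'   `[0, needle_length]` from the tip).
#' @param max_deflection Maximum lateral bow deflection at the tip, mm.
#' @param tip_depth Tip z coordinate above the template plane, mm.
#' @param proximal_overhang Needle length below the template plane, mm.
#' @param step Dwell / measurement step, mm.
#' @param seed RNG seed; output is deterministic per seed.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_needles = 4, grid_pitch = 5, needle_length = 50,
                         max_deflection = 1.5, tip_depth = 55,
                         proximal_overhang = 10, step = 5, seed = 1) {
  stopifnot(n_needles >= 1, grid_pitch > 0, needle_length > 0,
            max_deflection >= 0, tip_depth > needle_length)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Noise specification for simulated sessions
#'
#' Defaults are order-of-magnitude assumptions (submillimetre EMT sensor
#' noise, somewhat larger and anisotropic TRUS observer noise with depth
#' well constrained); all overridable.
#'
#' @param emt_sigma Per-axis EMT sensor noise SD, mm.
#' @param ref_trans_sigma Reference-pose translation noise SD, mm.
#' @param ref_rot_sigma_mrad Reference-pose rotation noise SD, mrad.
#' @param trus_sigma Per-axis TRUS observer noise SD, mm (length 3).
#' @param gross List of per-needle gross-error probabilities:
#'   `p_tip_depth`, `p_channel_swap`, `p_lateral`, with magnitudes
#'   `tip_depth_mm` and `lateral_mm`.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(emt_sigma = 0.05, ref_trans_sigma = 0.05,
                       ref_rot_sigma_mrad = 0.5,
                       trus_sigma = c(0.2, 0.2, 0.05),
                       gross = list(p_tip_depth = 0, p_channel_swap = 0,
                                    p_lateral = 0, tip_depth_mm = 10,
                                    lateral_mm = 5)) {
  stopifnot(emt_sigma >= 0, ref_trans_sigma >= 0, ref_rot_sigma_mrad >= 0,
            all(trus_sigma >= 0), length(trus_sigma) == 3)
  structure(list(emt_sigma = emt_sigma, ref_trans_sigma = ref_trans_sigma,
                 ref_rot_sigma_mrad = ref_rot_sigma_mrad,
                 trus_sigma = trus_sigma, gross = gross),
            class = "noise_spec")
}

random_quaternion <- function() {
  v <- stats::rnorm(4)
  quaternion(v[1], v[2], v[3], v[4])
}

random_rigid <- function(trans_range = 150) {
  rigid(random_quaternion(), stats::runif(3, -trans_range, trans_range))
}

# fixed template-holder calibration: reference sensor pose in the DICOM
# frame (a definite non-trivial transform standing in for the unpublished
# holder design values)
default_template_calibration <- function() {
  template_calibration(rigid(quat_from_axis_angle(c(0, 1, 0), pi / 6),
                             c(-65, 30, -20)))
}

# dense polyline of one needle: rows proximal -> distal; truth curves are
# quadratic bows (zero deflection at the proximal end, max at the tip)
needle_polyline <- function(base_xy, defl_vec, spec, n_dense = 4001) {
  z0 <- -spec$proximal_overhang; z1 <- spec$tip_depth
  z <- seq(z0, z1, length.out = n_dense)
  u <- (z - z0) / (z1 - z0)
  cbind(x = base_xy[1] + defl_vec[1] * u^2,
        y = base_xy[2] + defl_vec[2] * u^2,
        z = z)
}

# arc-length positions measured from the DISTAL tip along a dense polyline
polyline_points_at_tip_arc <- function(poly, s_from_tip) {
  seg <- sqrt(rowSums(diff(poly)^2))
  cum_from_tip <- rev(c(0, cumsum(rev(seg))))   # arc distance of row i to tip
  total <- cum_from_tip[1]
  t(vapply(s_from_tip, function(s) {
    s <- min(max(s, 0), total)
    i <- max(which(cum_from_tip >= s))
    if (i == nrow(poly)) return(poly[i, ])
    w <- (cum_from_tip[i] - s) / (cum_from_tip[i] - cum_from_tip[i + 1])
    poly[i, ] * (1 - w) + poly[i + 1, ] * w
  }, numeric(3)))
}

#' Generate a ground-truth phantom implant
#'
#' Needles start on template grid nodes near the array center, bow as
#' quadratic arcs, and carry dwells at `step` mm arc spacing from the tip
#' over `needle_length` mm.  The EMT frame is related to the DICOM frame by
#' a random rigid offset; the reference-sensor pose consistent with that
#' offset and the fixed template calibration is stored alongside.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"ground_truth"`: per-needle dense polylines and
#'   dwell matrices (DICOM and EMT frames), the true EMT-to-DICOM
#'   transform, true reference pose, template calibration, and the
#'   emission manifest.
#' @export
generate_implant <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  half <- 6  # 13 x 13 hole array
  holes <- as.matrix(expand.grid(ix = -half:half, iy = -half:half))
  d2 <- rowSums(holes^2)
  central <- holes[order(d2, stats::runif(nrow(holes))), , drop = FALSE]
  central <- central[central[, 1] != 0 | central[, 2] != 0, , drop = FALSE]
  picks <- central[seq_len(spec$n_needles), , drop = FALSE] * spec$grid_pitch
  n_dwell <- floor(spec$needle_length / spec$step + 1e-9) + 1
  s_dwell <- spec$step * (seq_len(n_dwell) - 1)
  needles <- lapply(seq_len(spec$n_needles), function(i) {
    ang <- stats::runif(1, 0, 2 * pi)
    mag <- stats::runif(1, 0, spec$max_deflection)
    poly <- needle_polyline(picks[i, ], mag * c(cos(ang), sin(ang)), spec)
    dw <- polyline_points_at_tip_arc(poly, s_dwell)
    colnames(dw) <- c("x", "y", "z")
    list(channel_id = i, base_xy = picks[i, ],
         deflection = mag * c(cos(ang), sin(ang)),
         polyline = poly, dwells_dicom = dw, arc_offsets = s_dwell)
  })
  transform <- random_rigid()              # EMT -> DICOM
  inv <- rigid_invert(transform)
  for (i in seq_along(needles))
    needles[[i]]$dwells_emt <- rigid_apply(inv, needles[[i]]$dwells_dicom)
  calib <- default_template_calibration()
  pose_tr <- rigid_compose(inv, calib$ref_in_dicom)  # sensor-local -> EMT
  gt <- structure(list(
    spec = spec, needles = needles, transform = transform,
    calibration = calib,
    reference_pose = reference_pose(pose_tr$t, pose_tr$q),
    manifest = list(n_channels = spec$n_needles, n_steps = n_dwell,
                    step = spec$step)),
    class = "ground_truth")
  check_ground_truth(gt)
  gt
}

check_ground_truth <- function(gt) {
  for (nd in gt$needles) {
    back <- rigid_apply(gt$transform, nd$dwells_emt)
    if (max(abs(back - nd$dwells_dicom)) > 1e-9)
      stop("ground truth inconsistent: EMT/DICOM dwell mismatch ",
           max(abs(back - nd$dwells_dicom)), " mm")
  }
  reg <- register_reference_sensor(gt$reference_pose, gt$calibration)
  p <- gt$needles[[1]]$dwells_emt
  if (max(abs(rigid_apply(reg$transform, p) -
              gt$needles[[1]]$dwells_dicom)) > 1e-9)
    stop("ground truth inconsistent: reference pose does not reproduce ",
         "the frame transform")
  invisible(gt)
}

perturb_pose <- function(pose, trans_sigma, rot_sigma_mrad) {
  dq <- if (rot_sigma_mrad > 0) {
    ang <- stats::rnorm(1, 0, rot_sigma_mrad / 1000)
    ax <- stats::rnorm(3)
    quat_from_axis_angle(ax, ang)
  } else quaternion()
  reference_pose(pose$position + stats::rnorm(3, 0, trans_sigma),
                 quat_multiply(dq, pose$orientation))
}

#' Simulate one step-and-shoot EMT session to a raw TSV file
#'
#' Writes `n_samples_per_point` noisy samples per (channel, step) with the
#' per-sample noisy reference pose in the pose columns; step 0 is the tip.
#' With `new_frame_offset = TRUE` the EMT frame offset is re-randomized
#' (afterloader reconnection / field-generator repositioning between
#' repeat sessions), consistent reference pose included.
#'
#' @param gt A `"ground_truth"`.
#' @param noise A [noise_spec()].
#' @param n_samples_per_point Samples per measurement point.
#' @param seed Session seed.
#' @param path Output TSV path.
#' @param new_frame_offset Draw a fresh EMT frame offset for this session.
#' @return Invisibly, a list: `path`, session `transform` (EMT to DICOM),
#'   clean session `pose`, and the emission manifest.
#' @export
simulate_emt_session <- function(gt, noise = noise_spec(),
                                 n_samples_per_point = 5, seed = 1,
                                 path = tempfile(fileext = ".tsv"),
                                 new_frame_offset = FALSE) {
  set.seed(seed)
  if (new_frame_offset) {
    transform <- random_rigid()
    inv <- rigid_invert(transform)
    pose_tr <- rigid_compose(inv, gt$calibration$ref_in_dicom)
    pose <- reference_pose(pose_tr$t, pose_tr$q)
  } else {
    transform <- gt$transform
    inv <- rigid_invert(transform)
    pose <- gt$reference_pose
  }
  rows <- list()
  for (nd in gt$needles) {
    emt_pts <- rigid_apply(inv, nd$dwells_dicom)
    for (k in seq_len(nrow(emt_pts))) {
      for (s in seq_len(n_samples_per_point)) {
        p <- emt_pts[k, ] + stats::rnorm(3, 0, noise$emt_sigma)
        rp <- perturb_pose(pose, noise$ref_trans_sigma,
                           noise$ref_rot_sigma_mrad)
        q <- unclass(rp$orientation)
        rows[[length(rows) + 1]] <- c(nd$channel_id, k - 1, p, q,
                                      rp$position, 1)
      }
    }
  }
  m <- do.call(rbind, rows)
  header <- c("channel", "step", "x", "y", "z", "qw", "qx", "qy", "qz",
              "rx", "ry", "rz", "quality")
  con <- file(path, "w")
  writeLines(c("# synthetic step-and-shoot EMT session (emtrecon simulator)",
               paste(header, collapse = "\t")), con)
  utils::write.table(format(m, digits = 15, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(list(path = path, transform = transform, pose = pose,
                 manifest = c(gt$manifest,
                              n_samples_per_point = n_samples_per_point)))
}

#' Simulate a TRUS observer reconstruction
#'
#' Dwell positions are the truth plus anisotropic observer noise; gross
#' reconstruction errors (tip-depth error, channel swap, lateral
#' misassignment) are injected per the noise menu or forced explicitly, and
#' logged.
#'
#' @param gt A `"ground_truth"`.
#' @param noise A [noise_spec()].
#' @param seed Observer seed.
#' @param force List of forced errors, e.g.
#'   `list(list(type = "tip_depth", channel = 2, delta_mm = 10))`,
#'   `list(list(type = "channel_swap", channels = c(1, 2)))`,
#'   `list(list(type = "lateral", channel = 1, delta_mm = 5))`.
#' @return A list: `recon` (dwell map), `errors` (data frame log).
#' @export
simulate_trus_observation <- function(gt, noise = noise_spec(), seed = 1,
                                      force = list()) {
  set.seed(seed)
  recon <- list()
  errlog <- list()
  for (nd in gt$needles) {
    pts <- nd$dwells_dicom +
      cbind(stats::rnorm(nrow(nd$dwells_dicom), 0, noise$trus_sigma[1]),
            stats::rnorm(nrow(nd$dwells_dicom), 0, noise$trus_sigma[2]),
            stats::rnorm(nrow(nd$dwells_dicom), 0, noise$trus_sigma[3]))
    recon[[as.character(nd$channel_id)]] <- pts
  }
  g <- noise$gross
  for (nd in gt$needles) {
    ch <- as.character(nd$channel_id)
    if (stats::runif(1) < g$p_tip_depth)
      force <- c(force, list(list(type = "tip_depth", channel = nd$channel_id,
                                  delta_mm = g$tip_depth_mm *
                                    sample(c(-1, 1), 1))))
    if (stats::runif(1) < g$p_lateral)
      force <- c(force, list(list(type = "lateral", channel = nd$channel_id,
                                  delta_mm = g$lateral_mm)))
  }
  if (length(gt$needles) >= 2 && stats::runif(1) < g$p_channel_swap)
    force <- c(force, list(list(
      type = "channel_swap",
      channels = sample(vapply(gt$needles, `[[`, integer(1), "channel_id"),
                        2))))
  for (e in force) {
    if (e$type == "tip_depth") {
      ch <- as.character(e$channel)
      nd <- gt$needles[[match(e$channel, vapply(gt$needles, `[[`,
                                                integer(1), "channel_id"))]]
      # a tip-depth error shifts the whole dwell train along the needle
      shifted <- polyline_points_at_tip_arc(nd$polyline,
                                            nd$arc_offsets + e$delta_mm)
      recon[[ch]] <- recon[[ch]] + (shifted - nd$dwells_dicom)
      errlog[[length(errlog) + 1]] <- data.frame(
        channel = e$channel, type = "tip_depth", magnitude = e$delta_mm)
    } else if (e$type == "channel_swap") {
      a <- as.character(e$channels[1]); b <- as.character(e$channels[2])
      tmp <- recon[[a]]; recon[[a]] <- recon[[b]]; recon[[b]] <- tmp
      errlog[[length(errlog) + 1]] <- data.frame(
        channel = e$channels[1], type = "channel_swap",
        magnitude = e$channels[2])
    } else if (e$type == "lateral") {
      ch <- as.character(e$channel)
      dir <- if (stats::runif(1) < 0.5) c(1, 0, 0) else c(0, 1, 0)
      recon[[ch]] <- sweep(recon[[ch]], 2, e$delta_mm * dir, "+")
      errlog[[length(errlog) + 1]] <- data.frame(
        channel = e$channel, type = "lateral", magnitude = e$delta_mm)
    } else stop("unknown gross error type: ", e$type)
  }
  list(recon = recon[order(as.integer(names(recon)))],
       errors = if (length(errlog)) do.call(rbind, errlog) else
         data.frame(channel = integer(), type = character(),
                    magnitude = numeric()))
}

ellipse_contour <- function(cx, cy, rx, ry, n = 48) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

#' Generate anatomy structures and a clinical-style plan for an implant
#'
#' Prostate: ellipsoid around the implant; urethra: central cylinder
#' (containing no dwells); bladder: superior-anterior ellipsoid; rectum:
#' posterior cylinder.  The plan carries the ground-truth dwell positions
#' with positive dwell times drawn once and fixed thereafter (weights are
#' exact 6-decimal cumulative fractions so files round-trip losslessly).
#'
#' @param gt A `"ground_truth"`.
#' @param seed Seed for dwell times.
#' @param prescription_gy Prescription dose recorded with the outputs, Gy.
#' @param plan_path,struct_path Optional output DICOM paths.
#' @return A list: `plan` (`"rtplan_model"`), `structs`
#'   (`"structure_set_model"`), `dwell_times` (list by channel),
#'   `prescription_gy`, plus file paths when written.
#' @export
generate_anatomy_and_plan <- function(gt, seed = 1, prescription_gy = 8.5,
                                      plan_path = NULL, struct_path = NULL) {
  set.seed(seed)
  all_dw <- do.call(rbind, lapply(gt$needles, `[[`, "dwells_dicom"))
  cx <- mean(all_dw[, 1]); cy <- mean(all_dw[, 2])
  cz <- mean(range(all_dw[, 3]))
  planes <- seq(cz - 24, cz + 24, by = 2.5)
  prostate <- list(name = "Prostate", number = 1, role = "target",
                   contours = lapply(planes, function(z) {
                     f <- sqrt(max(0, 1 - ((z - cz) / 26)^2))
                     list(z = z, xy = ellipse_contour(cx, cy, 24 * f, 21 * f))
                   }))
  prostate$contours <- Filter(function(ct)
    max(abs(ct$xy[, 1] - cx)) > 1, prostate$contours)
  urethra <- list(name = "Urethra", number = 2, role = "urethra",
                  contours = lapply(planes, function(z)
                    list(z = z, xy = ellipse_contour(cx, cy, 2.5, 2.5, 24))))
  bl_planes <- seq(cz + 27, cz + 45, by = 2.5)
  bladder <- list(name = "Bladder", number = 3, role = "bladder",
                  contours = lapply(bl_planes, function(z)
                    list(z = z, xy = ellipse_contour(cx, cy - 8, 28, 22))))
  rc_planes <- seq(cz - 24, cz + 24, by = 2.5)
  rectum <- list(name = "Rectum", number = 4, role = "rectum",
                 contours = lapply(rc_planes, function(z)
                   list(z = z, xy = ellipse_contour(cx, cy + 32, 11, 11, 32))))
  structs <- structure_set_model(list(prostate, urethra, bladder, rectum),
                                 label = "synthetic phantom anatomy")
  dwell_times <- list()
  channels <- lapply(gt$needles, function(nd) {
    n <- nrow(nd$dwells_dicom)
    times <- round(stats::runif(n, 5, 15), 1)
    total <- sum(times)
    cumw <- round(cumsum(times) / total, 6)
    cumw[n] <- 1
    dwell_times[[as.character(nd$channel_id)]] <<- times
    cp <- data.frame(
      index = seq_len(2 * n) - 1L,
      relative_position = rep(nd$arc_offsets, each = 2),
      x = rep(nd$dwells_dicom[, 1], each = 2),
      y = rep(nd$dwells_dicom[, 2], each = 2),
      z = rep(nd$dwells_dicom[, 3], each = 2),
      cumulative_time_weight = as.numeric(rbind(c(0, cumw[-n]), cumw)),
      weight_raw = "", stringsAsFactors = FALSE)
    list(channel_id = nd$channel_id, channel_total_time = total,
         channel_length = gt$spec$tip_depth + gt$spec$proximal_overhang,
         final_cumulative_time_weight = 1, control_points = cp)
  })
  plan <- rtplan_model(channels, label = "synthetic phantom plan",
                       description = paste(
                         "SYNTHETIC plan generated by the emtrecon phantom",
                         "simulator; prescription",
                         prescription_gy, "Gy"))
  out <- list(plan = plan, structs = structs, dwell_times = dwell_times,
              prescription_gy = prescription_gy)
  if (!is.null(plan_path)) {
    write_rtplan(plan, plan_path, uid_suffix = as.character(seed))
    out$plan_path <- plan_path
  }
  if (!is.null(struct_path)) {
    write_structure_set(structs, struct_path,
                        uid_suffix = as.character(seed))
    out$struct_path <- struct_path
  }
  out
}

#' Ground-truth dwell map
#'
#' @param gt A `"ground_truth"`.
#' @return A named list of dwell matrices (DICOM frame), by channel.
#' @export
truth_dwell_map <- function(gt) {
  out <- lapply(gt$needles, `[[`, "dwells_dicom")
  names(out) <- vapply(gt$needles, function(nd)
    as.character(nd$channel_id), character(1))
  out
}
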