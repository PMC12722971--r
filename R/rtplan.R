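# In-memory brachy RT Plan and RT Structure Set models plus DICOM I/O.
#
# Dwell encoding convention (normative for files written here): each dwell
# is a pair of brachy control points sharing one 3D position; the cumulative
# time weight is flat across non-dwell travel and steps across a dwell, so
# dwell time j = (w[2j] - w[2j-1]) / final_weight * channel_total_time
# (1-based rows).  Control points are ordered distal-first and
# ControlPointRelativePosition is the arc offset from the distal tip (mm).

SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

RTPLAN_CHANNEL_TAGS <- list(c(0x300A, 0x0282), c(0x300A, 0x0284),
                            c(0x300A, 0x0286), c(0x300A, 0x0288),
                            c(0x300A, 0x0110), c(0x300A, 0x02C8),
                            c(0x300A, 0x02D0))

#' Construct a brachy RT-plan model
#'
#' @param channels List of channel descriptions; each a list with
#'   `channel_id`, `channel_total_time` (s), `channel_length` (mm, may be
#'   `NA`), `final_cumulative_time_weight`, and `control_points`: a data
#'   frame with columns `index`, `relative_position` (mm from the distal
#'   tip), `x`, `y`, `z` (mm, DICOM frame) and `cumulative_time_weight`
#'   (non-decreasing, ending at the final weight).  An optional character
#'   column `weight_raw` preserves the exact decimal strings of the weights.
#' @param label Plan label.
#' @param description Free-text plan description.
#' @param nuclide Source isotope label.
#' @param ref_air_kerma_rate Reference air-kerma rate, uGy m^2 / h.
#' @return An object of class `"rtplan_model"`.
#' @export
rtplan_model <- function(channels, label = "emtrecon plan",
                         description = "",
                         nuclide = "Ir-192",
                         ref_air_kerma_rate = 40820) {
  ord <- order(vapply(channels, function(ch) ch$channel_id, numeric(1)))
  m <- structure(list(channels = channels[ord], label = label,
                      description = description, nuclide = nuclide,
                      ref_air_kerma_rate = ref_air_kerma_rate,
                      extra = list(), app_extra = list()),
                 class = "rtplan_model")
  m
}

validate_rtplan <- function(model) {
  for (ch in model$channels) {
    cp <- ch$control_points
    if (nrow(cp) < 2)
      stop("channel ", ch$channel_id, ": fewer than 2 control points")
    w <- cp$cumulative_time_weight
    if (any(diff(w) < -1e-12))
      stop("channel ", ch$channel_id,
           ": cumulative time weights are not non-decreasing")
    if (abs(w[length(w)] - ch$final_cumulative_time_weight) > 1e-9)
      stop("channel ", ch$channel_id,
           ": last control-point weight differs from the final cumulative ",
           "time weight")
    if (!all(is.finite(as.matrix(cp[, c("x", "y", "z")]))))
      stop("channel ", ch$channel_id, ": non-finite control-point position")
  }
  invisible(model)
}

#' Dwell positions and times of a plan
#'
#' Decodes the paired-control-point dwell convention into one [dwell_set()]
#' per channel plus the dwell times.
#'
#' @param model An `"rtplan_model"`.
#' @return A list per channel: `channel_id`, `dwells` ([dwell_set()]) and
#'   `times` (s).
#' @export
plan_dwells <- function(model) {
  lapply(model$channels, function(ch) {
    cp <- ch$control_points
    n <- nrow(cp)
    if (n %% 2 != 0)
      stop("channel ", ch$channel_id,
           ": odd control-point count; not paired-dwell encoded")
    a <- seq(1, n, by = 2); b <- a + 1
    pa <- as.matrix(cp[a, c("x", "y", "z")])
    pb <- as.matrix(cp[b, c("x", "y", "z")])
    if (max(abs(pa - pb)) > 1e-6)
      stop("channel ", ch$channel_id,
           ": paired control points do not share positions")
    w <- cp$cumulative_time_weight
    times <- (w[b] - w[a]) / ch$final_cumulative_time_weight *
      ch$channel_total_time
    offs <- cp$relative_position[a]
    step <- if (length(offs) > 1) stats::median(diff(offs)) else NA_real_
    list(channel_id = ch$channel_id,
         dwells = dwell_set(ch$channel_id, pa, offs, step),
         times = times)
  })
}

chan_to_elements <- function(ch) {
  cp_items <- lapply(seq_len(nrow(ch$control_points)), function(i) {
    row <- ch$control_points[i, ]
    wstr <- if (!is.null(ch$control_points$weight_raw) &&
                nzchar(row$weight_raw)) row$weight_raw else
                  ds_format(row$cumulative_time_weight)
    list(
      dcm_element(0x300A, 0x0112, "IS", as.character(row$index)),
      dcm_element(0x300A, 0x02D2, "DS", ds_format(row$relative_position)),
      dcm_element(0x300A, 0x02D4, "DS",
                  paste(ds_format(c(row$x, row$y, row$z)), collapse = "\\")),
      dcm_element(0x300A, 0x02D6, "DS", wstr)
    )
  })
  els <- list(
    dcm_element(0x300A, 0x0282, "IS", as.character(ch$channel_id)),
    dcm_element(0x300A, 0x0286, "DS",
                if (!is.null(ch$total_time_raw)) ch$total_time_raw else
                  ds_format(ch$channel_total_time)),
    dcm_element(0x300A, 0x0288, "CS", "STEPWISE"),
    dcm_element(0x300A, 0x0110, "IS",
                as.character(nrow(ch$control_points))),
    dcm_element(0x300A, 0x02C8, "DS",
                if (!is.null(ch$final_weight_raw)) ch$final_weight_raw else
                  ds_format(ch$final_cumulative_time_weight)),
    dcm_element(0x300A, 0x02D0, "SQ", cp_items)
  )
  if (is.finite(ch$channel_length))
    els <- c(els, list(dcm_element(0x300A, 0x0284, "DS",
                                   ds_format(ch$channel_length))))
  if (!is.null(ch$extra)) els <- c(els, ch$extra)
  els
}

#' Write a brachy RT Plan DICOM file
#'
#' Refuses to write a model violating its invariants (non-monotone weights,
#' mismatched final weight, < 2 control points).
#'
#' @param model An `"rtplan_model"`.
#' @param path Output path.
#' @param uid_suffix Deterministic suffix for the SOP instance UID.
#' @return `path`, invisibly.
#' @export
write_rtplan <- function(model, path, uid_suffix = "1") {
  validate_rtplan(model)
  sop_uid <- paste0(EMTRECON_UID_ROOT, ".5.", uid_suffix)
  src_item <- list(
    dcm_element(0x300A, 0x0212, "IS", "1"),
    dcm_element(0x300A, 0x0226, "LO", model$nuclide),
    dcm_element(0x300A, 0x022A, "DS", ds_format(model$ref_air_kerma_rate))
  )
  app_item <- c(list(
    dcm_element(0x300A, 0x0234, "IS", "1"),
    dcm_element(0x300A, 0x0280, "SQ",
                lapply(model$channels, chan_to_elements))
  ), model$app_extra)
  ds <- c(list(
    dcm_element(0x0008, 0x0016, "UI", SOP_RTPLAN),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_element(0x0008, 0x0070, "LO", "emtrecon"),
    dcm_element(0x300A, 0x0002, "SH", model$label),
    dcm_element(0x300A, 0x0004, "ST", model$description),
    dcm_element(0x300A, 0x0210, "SQ", list(src_item)),
    dcm_element(0x300A, 0x0230, "SQ", list(app_item))
  ), model$extra)
  dcm_write(ds, path, SOP_RTPLAN, sop_uid)
}

handled_plan_tags <- list(c(0x0008, 0x0016), c(0x0008, 0x0018),
                          c(0x0008, 0x0060), c(0x0008, 0x0070),
                          c(0x300A, 0x0002), c(0x300A, 0x0004),
                          c(0x300A, 0x0210), c(0x300A, 0x0230))

#' Read a brachy RT Plan DICOM file
#'
#' @param path Path to an RT Plan file (Explicit VR Little Endian).
#' @return An `"rtplan_model"`; unrecognized top-level elements are kept
#'   opaquely and written back by [write_rtplan()].
#' @export
read_rtplan <- function(path) {
  f <- dcm_read(path)
  ds <- f$dataset
  app_sq <- el_require(ds, 0x300A, 0x0230, "Application Setup Sequence")
  if (!length(app_sq$value)) stop("empty Application Setup Sequence")
  app <- app_sq$value[[1]]
  chan_sq <- el_require(app, 0x300A, 0x0280, "Channel Sequence")
  channels <- lapply(chan_sq$value, function(item) {
    chan_id <- as.integer(el_require(item, 0x300A, 0x0282,
                                     "Channel Number")$value)
    total_raw <- el_require(item, 0x300A, 0x0286, "Channel Total Time")$value
    final_raw <- el_require(item, 0x300A, 0x02C8,
                            "Final Cumulative Time Weight")$value
    len <- el_numbers(item, 0x300A, 0x0284)
    cps <- el_require(item, 0x300A, 0x02D0,
                      "Brachy Control Point Sequence")$value
    if (!length(cps)) stop("channel ", chan_id, ": no control points")
    cp <- do.call(rbind, lapply(cps, function(cpi) {
      pos <- el_numbers(cpi, 0x300A, 0x02D4)
      if (length(pos) != 3)
        stop("channel ", chan_id, ": Control Point 3D Position missing")
      data.frame(
        index = as.integer(el_require(cpi, 0x300A, 0x0112,
                                      "Control Point Index")$value),
        relative_position = as.numeric(
          el_numbers(cpi, 0x300A, 0x02D2) %||% NA_real_),
        x = pos[1], y = pos[2], z = pos[3],
        cumulative_time_weight = as.numeric(
          el_require(cpi, 0x300A, 0x02D6, "Cumulative Time Weight")$value),
        weight_raw = as.character(
          el_find(cpi, 0x300A, 0x02D6)$value),
        stringsAsFactors = FALSE)
    }))
    extra <- el_drop(item, RTPLAN_CHANNEL_TAGS)
    list(channel_id = chan_id,
         channel_total_time = as.numeric(total_raw),
         total_time_raw = as.character(total_raw),
         channel_length = if (is.null(len)) NA_real_ else len,
         final_cumulative_time_weight = as.numeric(final_raw),
         final_weight_raw = as.character(final_raw),
         control_points = cp, extra = extra)
  })
  src <- el_find(ds, 0x300A, 0x0210)
  nuclide <- "Ir-192"; rakr <- NA_real_
  if (!is.null(src) && length(src$value)) {
    nuclide <- el_string(src$value[[1]], 0x300A, 0x0226) %||% nuclide
    rakr <- el_numbers(src$value[[1]], 0x300A, 0x022A) %||% NA_real_
  }
  m <- rtplan_model(channels,
                    label = el_string(ds, 0x300A, 0x0002) %||% "",
                    description = el_string(ds, 0x300A, 0x0004) %||% "",
                    nuclide = nuclide, ref_air_kerma_rate = rakr)
  m$extra <- el_drop(ds, handled_plan_tags)
  m$app_extra <- el_drop(app, list(c(0x300A, 0x0234), c(0x300A, 0x0280)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replace channel geometry with EMT-reconstructed dwell positions
#'
#' Every matched channel gets its control-point 3D positions and relative
#' positions replaced by the reconstructed dwells (paired-control-point
#' convention); all dwell-time related fields (cumulative time weights,
#' channel total times, final weights) are carried over untouched, so the
#' adapted plan delivers the same dwell times at the corrected positions.
#'
#' @param plan An `"rtplan_model"`.
#' @param needles List of `"reconstructed_needle"` (or [dwell_set()])
#'   objects; channel ids must be a subset of the plan's.
#' @return The adapted `"rtplan_model"`.
#' @export
replace_reconstruction <- function(plan, needles) {
  dsets <- lapply(needles, function(nd)
    if (inherits(nd, "reconstructed_needle")) nd$dwells else nd)
  ids <- vapply(dsets, function(d) d$channel_id, integer(1))
  plan_ids <- vapply(plan$channels, function(ch) ch$channel_id, integer(1))
  if (length(setdiff(ids, plan_ids)))
    stop("needle channel(s) not in plan: ",
         paste(setdiff(ids, plan_ids), collapse = ", "))
  lens <- vapply(needles, function(nd)
    if (inherits(nd, "reconstructed_needle"))
      nd$spline$total_arc_length else NA_real_, numeric(1))
  mismatches <- character()
  out <- plan
  for (k in seq_along(plan$channels)) {
    ch <- plan$channels[[k]]
    j <- match(ch$channel_id, ids)
    if (is.na(j)) next
    d <- dsets[[j]]
    n_plan <- nrow(ch$control_points) / 2
    if (nrow(d$positions) != n_plan) {
      mismatches <- c(mismatches, sprintf(
        "channel %d: plan has %d dwells, reconstruction has %d",
        ch$channel_id, n_plan, nrow(d$positions)))
      next
    }
    rep_idx <- rep(seq_len(n_plan), each = 2)
    ch$control_points$x <- d$positions[rep_idx, 1]
    ch$control_points$y <- d$positions[rep_idx, 2]
    ch$control_points$z <- d$positions[rep_idx, 3]
    ch$control_points$relative_position <- d$arc_offsets[rep_idx]
    if (is.finite(lens[j])) ch$channel_length <- lens[j]
    out$channels[[k]] <- ch
  }
  if (length(mismatches))
    stop("dwell-count mismatch (dwell times are kept fixed, so counts ",
         "must agree):\n  ", paste(mismatches, collapse = "\n  "))
  unmatched <- setdiff(plan_ids, ids)
  if (length(unmatched))
    warning("plan channel(s) without reconstruction passed through: ",
            paste(unmatched, collapse = ", "))
  out
}

# ---------------------------------------------------------------- structures

#' Construct a structure-set model
#'
#' @param structures List of structures; each a list with `name`, `number`,
#'   `role` (one of target, urethra, bladder, rectum, other) and `contours`:
#'   a list of planar polygons, each `list(z = <mm>, xy = <n x 2 matrix>)`
#'   with at least 3 vertices.
#' @param label Structure set label.
#' @return An object of class `"structure_set_model"`.
#' @export
structure_set_model <- function(structures, label = "emtrecon structures") {
  for (s in structures) {
    for (ct in s$contours)
      if (nrow(ct$xy) < 3) stop("contour with < 3 vertices in ", s$name)
  }
  structures <- lapply(structures, function(s) {
    s$contours <- s$contours[order(vapply(s$contours, `[[`, numeric(1), "z"))]
    s
  })
  names(structures) <- vapply(structures, `[[`, character(1), "name")
  structure(list(structures = structures, label = label),
            class = "structure_set_model")
}

role_from_name <- function(name) {
  n <- tolower(name)
  if (grepl("prostate|target|ptv|ctv", n)) "target"
  else if (grepl("urethra", n)) "urethra"
  else if (grepl("bladder", n)) "bladder"
  else if (grepl("rectum", n)) "rectum"
  else "other"
}

#' Write an RT Structure Set DICOM file
#'
#' @param model A `"structure_set_model"`.
#' @param path Output path.
#' @param uid_suffix Deterministic SOP instance UID suffix.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(model, path, uid_suffix = "1") {
  sop_uid <- paste0(EMTRECON_UID_ROOT, ".3.", uid_suffix)
  roi_items <- lapply(model$structures, function(s) list(
    dcm_element(0x3006, 0x0022, "IS", as.character(s$number)),
    dcm_element(0x3006, 0x0026, "LO", s$name)
  ))
  contour_items <- lapply(model$structures, function(s) {
    cts <- lapply(s$contours, function(ct) {
      pts <- cbind(ct$xy, ct$z)
      list(
        dcm_element(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006, 0x0046, "IS", as.character(nrow(pts))),
        dcm_element(0x3006, 0x0050, "DS",
                    paste(ds_format(as.numeric(t(pts))), collapse = "\\"))
      )
    })
    list(dcm_element(0x3006, 0x0084, "IS", as.character(s$number)),
         dcm_element(0x3006, 0x0040, "SQ", cts))
  })
  obs_items <- lapply(model$structures, function(s) list(
    dcm_element(0x3006, 0x0082, "IS", as.character(s$number)),
    dcm_element(0x3006, 0x0084, "IS", as.character(s$number)),
    dcm_element(0x3006, 0x00A4, "CS",
                if (s$role == "target") "PTV" else "ORGAN")
  ))
  ds <- list(
    dcm_element(0x0008, 0x0016, "UI", SOP_RTSTRUCT),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x0008, 0x0070, "LO", "emtrecon"),
    dcm_element(0x3006, 0x0002, "SH", model$label),
    dcm_element(0x3006, 0x0020, "SQ", unname(roi_items)),
    dcm_element(0x3006, 0x0039, "SQ", unname(contour_items)),
    dcm_element(0x3006, 0x0080, "SQ", unname(obs_items))
  )
  dcm_write(ds, path, SOP_RTSTRUCT, sop_uid)
}

#' Read an RT Structure Set DICOM file
#'
#' @param path Path to an RT Structure Set file.
#' @return A `"structure_set_model"`; roles are inferred from ROI names
#'   (urethra / bladder / rectum / target synonyms, else `other`).
#' @export
read_structure_set <- function(path) {
  f <- dcm_read(path)
  ds <- f$dataset
  rois <- el_require(ds, 0x3006, 0x0020, "Structure Set ROI Sequence")$value
  names_by_num <- list()
  for (item in rois) {
    num <- as.integer(el_require(item, 0x3006, 0x0022, "ROI Number")$value)
    names_by_num[[as.character(num)]] <-
      el_string(item, 0x3006, 0x0026) %||% paste0("ROI", num)
  }
  csq <- el_require(ds, 0x3006, 0x0039, "ROI Contour Sequence")$value
  structures <- lapply(csq, function(item) {
    num <- as.integer(el_require(item, 0x3006, 0x0084,
                                 "Referenced ROI Number")$value)
    name <- names_by_num[[as.character(num)]] %||% paste0("ROI", num)
    cts <- lapply(el_require(item, 0x3006, 0x0040,
                             "Contour Sequence")$value, function(ct) {
      v <- el_numbers(ct, 0x3006, 0x0050)
      m <- matrix(v, ncol = 3, byrow = TRUE)
      list(z = m[1, 3], xy = m[, 1:2, drop = FALSE])
    })
    list(name = name, number = num, role = role_from_name(name),
         contours = cts)
  })
  structure_set_model(structures,
                      label = el_string(ds, 0x3006, 0x0002) %||% "")
}

#' @export
print.rtplan_model <- function(x, ...) {
  cat(sprintf("RT plan '%s': %d channel(s), %s source\n", x$label,
              length(x$channels), x$nuclide))
  for (ch in x$channels)
    cat(sprintf("  channel %d: %d control points, total time %.1f s\n",
                ch$channel_id, nrow(ch$control_points),
                ch$channel_total_time))
  invisible(x)
}

#' @export
print.structure_set_model <- function(x, ...) {
  cat(sprintf("structure set '%s': %d structure(s)\n", x$label,
              length(x$structures)))
  for (s in x$structures)
    cat(sprintf("  %s (%s): %d contour plane(s)\n", s$name, s$role,
                length(s$contours)))
  invisible(x)
}
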