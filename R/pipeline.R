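# End-to-end workflow orchestration with YAML run configuration, per-stage
# logging and a deterministic run manifest.
#
# Workflow 2 ("reconstruction and registration"): parse raw EMT file ->
# aggregate -> register via the 6DoF reference sensor -> spline
# reconstruction -> replace geometry in the baseline plan -> write the
# adapted plan.  Workflow 1 differs only in registration: a least-squares
# rigid fit to correspondences with a TRUS-based (pre)reconstruction.

CONFIG_KEYS <- list(
  top = c("paths", "acquisition", "registration", "reconstruction",
          "dosimetry", "seed"),
  paths = c("raw_emt", "plan", "structures", "correspondences", "out_dir"),
  acquisition = c("step_spacing", "n_steps", "outlier_mad_threshold",
                  "min_samples_per_point", "quality_min"),
  registration = c("method", "calibration"),
  reconstruction = c("control_spacing", "step", "tip_offset",
                     "template_plane_z"),
  dosimetry = c("grid_spacing", "prescription_gy", "source_table"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Read and validate a run configuration
#'
#' YAML with sections `paths`, `acquisition`, `registration` (`method`:
#' `reference_sensor` or `point_correspondence`; `calibration`: 12-number
#' row-major rigid matrix), `reconstruction`, `dosimetry`, `seed`.  Unknown
#' keys are rejected.
#'
#' @param path YAML file path, or a list (validated in place).
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  check_keys(cfg, CONFIG_KEYS$top, "config")
  for (sec in intersect(names(cfg), names(CONFIG_KEYS)[-1]))
    check_keys(cfg[[sec]], CONFIG_KEYS[[sec]], sec)
  if (!is.null(cfg$registration$method) &&
      !cfg$registration$method %in% c("reference_sensor",
                                      "point_correspondence"))
    stop("registration method must be reference_sensor or ",
         "point_correspondence")
  cfg
}

cfg_acquisition <- function(cfg) {
  a <- cfg$acquisition %||% list()
  do.call(acquisition_config, a)
}

stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)),
    warning = function(w) {
      log$warnings[[length(log$warnings) + 1]] <-
        paste0(name, ": ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  log$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  res
}

write_manifest <- function(log, cfg_path, inputs, out_dir) {
  manifest <- list(
    tool = paste0("emtrecon ",
                  as.character(utils::packageVersion("emtrecon"))),
    config_hash = if (!is.null(cfg_path) && is.character(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA,
    input_hashes = as.list(tools::md5sum(unlist(inputs))),
    timings_s = log$timings,
    warnings = unlist(log$warnings) %||% character())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

run_workflow <- function(config, workflow) {
  cfg <- read_run_config(config)
  out_dir <- cfg$paths$out_dir %||% stop("paths.out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- new.env()
  log$timings <- list(); log$warnings <- list()

  raw <- stage("parse", log, parse_emt_raw(cfg$paths$raw_emt))
  series <- stage("aggregate", log,
                  aggregate_series(raw, cfg_acquisition(cfg)))
  reg <- stage("register", log, {
    if (workflow == 2) {
      if (!raw$has_reference_pose)
        stop("reference-sensor registration needs the pose columns ",
             "(qw qx qy qz rx ry rz) in the raw EMT file")
      if (is.null(cfg$registration$calibration))
        stop("registration.calibration (12-number rigid matrix) missing")
      calib <- template_calibration(
        rigid_from_matrix12(as.numeric(cfg$registration$calibration)))
      register_reference_sensor(session_reference_pose(raw), calib)
    } else {
      pairs <- load_correspondences(cfg, series)
      if (nrow(pairs) < 3)
        stop("need >= 3 correspondences, got ", nrow(pairs))
      register_point_correspondence(pairs)
    }
  })
  series_d <- stage("transform", log, transform_series(series, reg))
  plan <- if (!is.null(cfg$paths$plan))
    stage("read_plan", log, read_rtplan(cfg$paths$plan)) else NULL
  rc <- cfg$reconstruction %||% list()
  needles <- stage("reconstruct", log, {
    # a baseline plan fixes the dwell count per channel (dwell times are
    # carried over unchanged, so counts must match)
    counts <- if (!is.null(plan)) {
      ids <- vapply(plan$channels, `[[`, integer(1), "channel_id")
      stats::setNames(vapply(plan$channels, function(ch)
        nrow(ch$control_points) / 2, numeric(1)), ids)
    } else NULL
    lapply(series_d, function(s) reconstruct_needle(
      s,
      control_spacing = rc$control_spacing %||% 5,
      step = rc$step %||% 5,
      tip_offset = rc$tip_offset %||% 0,
      n_dwells = if (!is.null(counts))
        counts[[as.character(s$channel_id)]] else NULL,
      template_plane_z = rc$template_plane_z))
  })
  recon_tsv <- file.path(out_dir, "reconstruction.tsv")
  write_reconstruction_tsv(needles, recon_tsv)

  outputs <- list(reconstruction = recon_tsv)
  if (!is.null(plan)) {
    adapted <- stage("replace_reconstruction", log,
                     replace_reconstruction(plan, needles))
    plan_out <- file.path(out_dir, "adapted_plan.dcm")
    stage("write_plan", log, write_rtplan(
      adapted, plan_out,
      uid_suffix = as.character(cfg$seed %||% 1)))
    outputs$adapted_plan <- plan_out
    cmp <- stage("compare", log, {
      m <- match_and_ed(plan_dwells(adapted), plan_dwells(plan))
      utils::write.table(
        format(m, digits = 10, scientific = FALSE, trim = TRUE),
        file.path(out_dir, "dwell_comparison.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      agreement_report(m)
    })
    outputs$comparison <- file.path(out_dir, "dwell_comparison.tsv")
    outputs$agreement <- cmp
    if (!is.null(cfg$paths$structures) && !is.null(cfg$dosimetry)) {
      dvh <- stage("dvh", log, {
        structs <- read_structure_set(cfg$paths$structures)
        dspec <- cfg$dosimetry
        src <- source_model(g_table = dspec$source_table)
        grid <- default_grid_for(structs,
                                 spacing = dspec$grid_spacing %||% 2,
                                 prescription_gy = dspec$prescription_gy)
        metric_difference(plan_dwells(adapted), plan_dwells(plan),
                          structs, src, grid)
      })
      utils::write.table(
        format(dvh, digits = 8, scientific = FALSE, trim = TRUE),
        file.path(out_dir, "dvh_comparison.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      outputs$dvh <- file.path(out_dir, "dvh_comparison.tsv")
    }
  }
  write_manifest(log, if (is.character(config)) config else NULL,
                 Filter(Negate(is.null),
                        cfg$paths[c("raw_emt", "plan", "structures")]),
                 out_dir)
  invisible(c(outputs, list(registration = reg, needles = needles,
                            warnings = unlist(log$warnings))))
}

load_correspondences <- function(cfg, series) {
  path <- cfg$paths$correspondences
  if (!is.null(path)) {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    req <- c("channel", "step", "ex", "ey", "ez", "dx", "dy", "dz")
    if (!all(req %in% names(df)))
      stop("correspondence TSV must have columns: ",
           paste(req, collapse = " "))
    return(df)
  }
  # else: use the baseline plan's dwells as the TRUS (pre)reconstruction,
  # matched by (channel, step index)
  if (is.null(cfg$paths$plan))
    stop("workflow 1 needs paths.correspondences or a baseline paths.plan")
  plan <- read_rtplan(cfg$paths$plan)
  pd <- plan_dwells(plan)
  rows <- list()
  for (s in series) {
    j <- match(s$channel_id, vapply(pd, `[[`, integer(1), "channel_id"))
    if (is.na(j)) next
    n <- min(nrow(s$points), nrow(pd[[j]]$dwells$positions))
    rows[[length(rows) + 1]] <- data.frame(
      channel = s$channel_id, step = seq_len(n) - 1L,
      ex = s$points[1:n, 1], ey = s$points[1:n, 2], ez = s$points[1:n, 3],
      dx = pd[[j]]$dwells$positions[1:n, 1],
      dy = pd[[j]]$dwells$positions[1:n, 2],
      dz = pd[[j]]$dwells$positions[1:n, 3])
  }
  do.call(rbind, rows)
}

#' A dose grid covering a structure set
#'
#' @param structs A [structure_set_model()].
#' @param spacing Voxel spacing, mm.
#' @param prescription_gy Prescription dose, Gy.
#' @param margin Margin around the structures, mm.
#' @return A [dose_grid()].
#' @export
default_grid_for <- function(structs, spacing = 2, prescription_gy,
                             margin = 3) {
  pts <- do.call(rbind, lapply(structs$structures, function(s)
    do.call(rbind, lapply(s$contours, function(ct)
      cbind(ct$xy, ct$z)))))
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  dose_grid(lo, spacing, dims, prescription_gy)
}

#' Run the fully automated workflow (6DoF reference-sensor registration)
#'
#' @param config Path to a YAML run configuration, or an equivalent list.
#' @return Invisibly, a list of output paths, the registration result, the
#'   reconstructed needles and collected warnings.
#' @export
run_workflow2 <- function(config) run_workflow(config, 2)

#' Run the point-correspondence workflow (TRUS pre-reconstruction based)
#'
#' @param config Path to a YAML run configuration, or an equivalent list.
#' @return As [run_workflow2()]; the registration RMS residual is logged.
#' @export
run_workflow1 <- function(config) run_workflow(config, 1)

#' Run the four-repeat reproducibility protocol on simulated sessions
#'
#' Repeats the entire reconstruction chain `n_repeats` times on freshly
#' simulated EMT sessions of the same implant, each with a re-randomized
#' EMT frame offset, and reports the k = 2 reproducibility of the resulting
#' dwell positions.
#'
#' @param gt A `"ground_truth"` implant.
#' @param noise A [noise_spec()].
#' @param n_repeats Number of repeat sessions.
#' @param n_samples_per_point Raw samples per measurement point.
#' @param seed Base seed; session r uses `seed + r`.
#' @return A list: `report` (a `"reproducibility_report"`), `recons`.
#' @export
repro_study <- function(gt, noise = noise_spec(), n_repeats = 4,
                        n_samples_per_point = 5, seed = 1) {
  recons <- lapply(seq_len(n_repeats), function(r) {
    ses <- simulate_emt_session(gt, noise, n_samples_per_point,
                                seed = seed + r, new_frame_offset = TRUE)
    on.exit(unlink(ses$path))
    raw <- parse_emt_raw(ses$path)
    series <- aggregate_series(raw, acquisition_config(
      step_spacing = gt$manifest$step, n_steps = gt$manifest$n_steps))
    reg <- register_reference_sensor(session_reference_pose(raw),
                                     gt$calibration)
    reconstruct_implant(transform_series(series, reg),
                        step = gt$manifest$step,
                        n_dwells = gt$manifest$n_steps)
  })
  list(report = reproducibility_k2(recons), recons = recons)
}
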