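make_plan_fixture <- function(seed = 3) {
  gt <- generate_implant(phantom_spec(seed = seed))
  generate_anatomy_and_plan(gt, seed = seed,
                            plan_path = tempfile(fileext = ".dcm"),
                            struct_path = tempfile(fileext = ".dcm"))
}

test_that("RT plan DICOM write/read round trips losslessly", {
  ap <- make_plan_fixture()
  m <- read_rtplan(ap$plan_path)
  expect_s3_class(m, "rtplan_model")
  expect_length(m$channels, 4)
  for (k in 1:4) {
    src <- ap$plan$channels[[k]]; got <- m$channels[[k]]
    expect_equal(got$channel_id, src$channel_id)
    expect_equal(got$channel_total_time, src$channel_total_time,
                 tolerance = 1e-9)
    expect_equal(got$final_cumulative_time_weight, 1)
    expect_equal(nrow(got$control_points), nrow(src$control_points))
    expect_lt(max(abs(as.matrix(got$control_points[, c("x", "y", "z")]) -
                        as.matrix(src$control_points[, c("x", "y", "z")]))),
              1e-6)
    expect_equal(got$control_points$cumulative_time_weight,
                 src$control_points$cumulative_time_weight)
  }
  # second generation round trip: write the read model and re-read
  p2 <- tempfile(fileext = ".dcm")
  write_rtplan(m, p2)
  m2 <- read_rtplan(p2)
  expect_equal(m2$channels[[1]]$control_points$weight_raw,
               m$channels[[1]]$control_points$weight_raw)
  expect_equal(m2$channels[[2]]$control_points$x,
               m$channels[[2]]$control_points$x, tolerance = 1e-9)
})

test_that("the written RT plan is readable by an independent DICOM
           implementation", {
  ap <- make_plan_fixture(seed = 6)
  script <- tempfile(fileext = ".py")
  out <- tempfile()
  writeLines(c(
    "import pydicom, sys, json",
    sprintf("p = pydicom.dcmread(r'%s')", ap$plan_path),
    "ch = p.ApplicationSetupSequence[0].ChannelSequence",
    "cp = ch[0].BrachyControlPointSequence",
    "json.dump({'modality': str(p.Modality), 'n_channels': len(ch),",
    "  'n_cp': len(cp), 'pos': [float(v) for v in cp[3].ControlPoint3DPosition],",
    "  'w': float(cp[3].CumulativeTimeWeight),",
    "  'total': float(ch[0].ChannelTotalTime)},",
    sprintf("  open(r'%s', 'w'))", out)), script)
  status <- system2("python", script)
  expect_equal(status, 0)
  got <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(got$modality, "RTPLAN")
  expect_equal(got$n_channels, 4)
  ch1 <- ap$plan$channels[[1]]
  expect_equal(got$n_cp, nrow(ch1$control_points))
  expect_equal(got$pos,
               as.numeric(ch1$control_points[4, c("x", "y", "z")]),
               tolerance = 1e-6)
  expect_equal(got$w, ch1$control_points$cumulative_time_weight[4],
               tolerance = 1e-12)
  expect_equal(got$total, ch1$channel_total_time, tolerance = 1e-9)
})

test_that("replace_reconstruction swaps geometry and never touches time", {
  ap <- make_plan_fixture(seed = 4)
  plan <- read_rtplan(ap$plan_path)
  pd <- plan_dwells(plan)
  # identity replacement: same geometry back
  same <- replace_reconstruction(plan, lapply(pd, `[[`, "dwells"))
  expect_equal(same$channels[[1]]$control_points,
               plan$channels[[1]]$control_points, tolerance = 1e-12)
  # shift all needles +2 mm in z
  shifted <- lapply(pd, function(x) {
    d <- x$dwells; d$positions[, 3] <- d$positions[, 3] + 2; d
  })
  adapted <- replace_reconstruction(plan, shifted)
  for (k in seq_along(plan$channels)) {
    a <- adapted$channels[[k]]; b <- plan$channels[[k]]
    expect_equal(a$control_points$z, b$control_points$z + 2,
                 tolerance = 1e-9)
    expect_identical(a$control_points$weight_raw,
                     b$control_points$weight_raw)
    expect_identical(a$total_time_raw, b$total_time_raw)
    expect_identical(a$final_weight_raw, b$final_weight_raw)
  }
  # dwell-count mismatch is fatal and names the channel
  short <- lapply(pd[1], function(x) {
    d <- x$dwells; d$positions <- d$positions[1:5, ]; d
  })
  expect_error(suppressWarnings(replace_reconstruction(plan, short)),
               "channel 1")
  # unmatched plan channels pass through with a warning
  expect_warning(replace_reconstruction(plan, lapply(pd[1:2], `[[`,
                                                     "dwells")),
                 "passed through")
})

test_that("invalid models are refused at write time; truncated files fail
           to parse", {
  ap <- make_plan_fixture(seed = 5)
  bad <- ap$plan
  bad$channels[[1]]$control_points$cumulative_time_weight <-
    rev(bad$channels[[1]]$control_points$cumulative_time_weight)
  expect_error(write_rtplan(bad, tempfile(fileext = ".dcm")),
               "non-decreasing")
  b <- readBin(ap$plan_path, raw(), file.info(ap$plan_path)$size)
  trunc_path <- tempfile(fileext = ".dcm")
  writeBin(b[1:floor(length(b) / 2)], trunc_path)
  expect_error(read_rtplan(trunc_path))
  not_dicom <- tempfile()
  writeLines("hello", not_dicom)
  expect_error(read_rtplan(not_dicom), "not a DICOM")
})

test_that("structure sets round trip with roles and sorted planes", {
  ap <- make_plan_fixture(seed = 7)
  st <- read_structure_set(ap$struct_path)
  expect_setequal(names(st$structures),
                  c("Prostate", "Urethra", "Bladder", "Rectum"))
  expect_equal(st$structures$Prostate$role, "target")
  expect_equal(st$structures$Rectum$role, "rectum")
  zs <- vapply(st$structures$Prostate$contours, `[[`, numeric(1), "z")
  expect_true(all(diff(zs) > 0))
  src_ct <- ap$structs$structures$Urethra$contours[[1]]
  got_ct <- st$structures$Urethra$contours[[1]]
  expect_equal(got_ct$z, src_ct$z, tolerance = 1e-9)
  expect_lt(max(abs(got_ct$xy - src_ct$xy)), 1e-6)
})
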