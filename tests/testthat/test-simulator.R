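test_that("implant generation is deterministic and internally consistent", {
  g1 <- generate_implant(phantom_spec(seed = 9))
  g2 <- generate_implant(phantom_spec(seed = 9))
  expect_identical(g1$needles[[1]]$dwells_dicom,
                   g2$needles[[1]]$dwells_dicom)
  expect_identical(rigid_to_matrix12(g1$transform),
                   rigid_to_matrix12(g2$transform))
  g3 <- generate_implant(phantom_spec(seed = 10))
  expect_false(identical(g1$needles[[1]]$dwells_dicom,
                         g3$needles[[1]]$dwells_dicom))
  # default protocol: 4 needles x 11 dwells
  dw <- do.call(rbind, lapply(g1$needles, `[[`, "dwells_dicom"))
  expect_equal(nrow(dw), 44)
  # self-consistency: EMT-frame dwells map back through the true transform
  for (nd in g1$needles)
    expect_lt(max(abs(rigid_apply(g1$transform, nd$dwells_emt) -
                        nd$dwells_dicom)), 1e-9)
})

test_that("zero deflection gives straight needles with arithmetic dwell
           depths", {
  gt <- generate_implant(phantom_spec(max_deflection = 0, seed = 2))
  for (nd in gt$needles) {
    expect_lt(max(abs(sweep(nd$dwells_dicom[, 1:2], 2,
                            nd$dwells_dicom[1, 1:2]))), 1e-12)
    expect_equal(diff(nd$dwells_dicom[, 3]), rep(-5, 10),
                 tolerance = 1e-9)
  }
})

test_that("simulated sessions honour seed determinism and the noise model", {
  gt <- generate_implant(phantom_spec(seed = 3))
  p1 <- tempfile(); p2 <- tempfile()
  simulate_emt_session(gt, noise_spec(), 5, seed = 7, path = p1)
  simulate_emt_session(gt, noise_spec(), 5, seed = 7, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  # noiseless aggregation reproduces the EMT-frame truth exactly
  p0 <- tempfile()
  simulate_emt_session(gt, noise_spec(emt_sigma = 0, ref_trans_sigma = 0,
                                      ref_rot_sigma_mrad = 0),
                       3, seed = 8, path = p0)
  series <- aggregate_series(parse_emt_raw(p0), acquisition_config())
  for (k in seq_along(series))
    expect_lt(max(abs(series[[k]]$points - gt$needles[[k]]$dwells_emt)),
              1e-9)
  # noisy aggregation stays within the standard-error scale of truth
  set.seed(60)
  ok <- replicate(10, {
    pn <- tempfile()
    simulate_emt_session(gt, noise_spec(emt_sigma = 0.05), 5,
                         seed = sample.int(1e6, 1), path = pn)
    s <- aggregate_series(parse_emt_raw(pn), acquisition_config())
    errs <- mapply(function(a, b) max(abs(a$points - b$dwells_emt)),
                   s, gt$needles)
    unlink(pn)
    mean(errs < 0.1)
  })
  expect_gte(mean(ok), 0.99)
})

test_that("TRUS observation reproduces truth when clean and logs injected
           gross errors", {
  gt <- generate_implant(phantom_spec(seed = 4))
  clean <- simulate_trus_observation(gt, noise_spec(trus_sigma = c(0, 0, 0)),
                                     seed = 1)
  expect_equal(clean$recon, truth_dwell_map(gt), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nrow(clean$errors), 0)
  # forced 10 mm tip-depth error
  obs <- simulate_trus_observation(
    gt, noise_spec(trus_sigma = c(0, 0, 0)), seed = 2,
    force = list(list(type = "tip_depth", channel = 2, delta_mm = 10)))
  m <- match_and_ed(obs$recon, truth_dwell_map(gt))
  ed2 <- m$ed[m$channel == 2]
  expect_true(all(abs(ed2 - 10) < 0.5))
  expect_true(all(m$ed[m$channel != 2] < 1e-9))
  expect_equal(obs$errors$type, "tip_depth")
  # channel swap: matched-by-index EDs equal the inter-needle separation
  sw <- simulate_trus_observation(
    gt, noise_spec(trus_sigma = c(0, 0, 0)), seed = 3,
    force = list(list(type = "channel_swap", channels = c(1, 2))))
  msw <- match_and_ed(sw$recon, truth_dwell_map(gt))
  sep <- sqrt(rowSums((gt$needles[[1]]$dwells_dicom -
                         gt$needles[[2]]$dwells_dicom)^2))
  expect_equal(msw$ed[msw$channel == 1], sep, tolerance = 1e-9)
  expect_equal(msw$ed[msw$channel == 2], sep, tolerance = 1e-9)
})

test_that("generated anatomy keeps dwells out of the urethra and the plan
           round trips", {
  gt <- generate_implant(phantom_spec(seed = 5))
  ap <- generate_anatomy_and_plan(gt, seed = 5,
                                  plan_path = tempfile(fileext = ".dcm"),
                                  struct_path = tempfile(fileext = ".dcm"))
  dw <- do.call(rbind, lapply(gt$needles, `[[`, "dwells_dicom"))
  ur <- ap$structs$structures$Urethra$contours[[1]]
  cx <- mean(ur$xy[, 1]); cy <- mean(ur$xy[, 2])
  expect_true(all(sqrt((dw[, 1] - cx)^2 + (dw[, 2] - cy)^2) > 2.5))
  # dwell times positive and consistent with the cumulative weights
  plan <- read_rtplan(ap$plan_path)
  pd <- plan_dwells(plan)
  for (k in seq_along(pd)) {
    expect_true(all(pd[[k]]$times > 0))
    expect_equal(pd[[k]]$times, ap$dwell_times[[as.character(k)]],
                 tolerance = 1e-3)
    expect_lt(max(abs(pd[[k]]$dwells$positions -
                        gt$needles[[k]]$dwells_dicom)), 1e-6)
  }
  st <- read_structure_set(ap$struct_path)
  expect_length(st$structures, 4)
})
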