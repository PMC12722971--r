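test_that("reference-sensor registration is exact, including analytic
           cases", {
  id <- register_reference_sensor(reference_pose(c(0, 0, 0), quaternion()),
                                  template_calibration(rigid_identity()))
  expect_equal(rigid_apply(id$transform, c(1, 2, 3)), c(1, 2, 3),
               tolerance = 1e-12)
  expect_equal(id$rms_residual, 0)
  expect_equal(id$method, "reference_sensor")
  # sensor sitting at (10,0,0) in EMT, calibration identity: EMT (10,0,0)
  # maps to the DICOM origin
  tr <- register_reference_sensor(
    reference_pose(c(10, 0, 0), quaternion()),
    template_calibration(rigid_identity()))
  expect_equal(rigid_apply(tr$transform, c(10, 0, 0)), c(0, 0, 0),
               tolerance = 1e-12)
  bad <- reference_pose(c(0, 0, 0), quaternion())
  bad$orientation <- structure(c(2, 0, 0, 0), class = "quaternion")
  expect_error(register_reference_sensor(
    bad, template_calibration(rigid_identity())), "degenerate")
})

test_that("reference-sensor registration recovers random frame offsets to
           machine precision", {
  set.seed(21)
  calib <- template_calibration(rand_rigid())
  for (i in 1:20) {
    true_offset <- rand_rigid()                     # EMT -> DICOM
    pose_tr <- rigid_compose(rigid_invert(true_offset), calib$ref_in_dicom)
    pose <- reference_pose(pose_tr$t, pose_tr$q)
    reg <- register_reference_sensor(pose, calib)
    p <- rand_points(100)
    expect_lt(max(abs(rigid_apply(reg$transform, p) -
                        rigid_apply(true_offset, p))), 1e-9)
  }
})

test_that("point-correspondence fit solves exact and noisy problems", {
  # exact: 90 degree z rotation + (5,5,0)
  tr_true <- rigid(quat_from_axis_angle(c(0, 0, 1), pi / 2), c(5, 5, 0))
  emt <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  fit <- register_point_correspondence(emt, rigid_apply(tr_true, emt))
  expect_lt(fit$rms_residual, 1e-9)
  expect_lt(max(abs(rigid_apply(fit$transform, emt) -
                      rigid_apply(tr_true, emt))), 1e-9)
  # identity pairs
  fid <- register_point_correspondence(emt, emt)
  expect_lt(fid$rms_residual, 1e-12)
  # noisy: per-axis sigma 0.2 mm on 44 pairs; rms residual concentrates
  # around sigma*sqrt(3)*sqrt(1 - 6/(3n)) ~ 0.338 and a held-out point
  # maps close to truth
  set.seed(22)
  in_band <- held_out_ok <- logical(50)
  for (i in 1:50) {
    tr <- rand_rigid()
    pts <- rand_points(45, range = 30)
    noisy <- rigid_apply(tr, pts) + matrix(rnorm(45 * 3, 0, 0.2), ncol = 3)
    f <- register_point_correspondence(pts[1:44, ], noisy[1:44, ])
    in_band[i] <- f$rms_residual > 0.25 && f$rms_residual < 0.45
    held_out_ok[i] <- sqrt(sum((rigid_apply(f$transform, pts[45, ]) -
                                  rigid_apply(tr, pts[45, ]))^2)) < 0.3
  }
  expect_gte(mean(in_band), 0.9)
  expect_gte(mean(held_out_ok), 0.95)
})

test_that("degenerate correspondence sets are rejected; rotations stay
           proper", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(register_point_correspondence(line, line), "collinear")
  expect_error(register_point_correspondence(line[1:2, ], line[1:2, ]),
               ">= 3")
  # near-reflection configurations must still yield det +1
  set.seed(23)
  for (i in 1:20) {
    pts <- rand_points(4, range = 10)
    noisy <- rand_points(4, range = 10)  # unrelated -> worst case
    f <- register_point_correspondence(pts, noisy)
    expect_equal(det(quat_to_matrix(f$transform$q)), 1, tolerance = 1e-9)
  }
})

test_that("transform_series preserves structure and distances", {
  pts <- straight_series_points()
  s <- measurement_series(3, pts, 5)
  id <- register_reference_sensor(reference_pose(c(0, 0, 0), quaternion()),
                                  template_calibration(rigid_identity()))
  expect_equal(transform_series(s, id)$points, s$points,
               tolerance = 1e-12)
  set.seed(24)
  tr <- rand_rigid()
  reg <- structure(list(transform = tr, rms_residual = 0,
                        method = "reference_sensor"),
                   class = "registration_result")
  s2 <- transform_series(list(s, measurement_series(5, pts + 10, 5)), reg)
  expect_equal(s2[[1]]$channel_id, 3)
  # chord lengths and inter-needle distances survive
  expect_equal(sqrt(rowSums(diff(s2[[1]]$points)^2)),
               sqrt(rowSums(diff(pts)^2)), tolerance = 1e-9)
  d0 <- sqrt(rowSums((pts - (pts + 10))^2))
  d1 <- sqrt(rowSums((s2[[1]]$points - s2[[2]]$points)^2))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("noiseless workflows agree: correspondence fit on all dwells
           reproduces the reference-sensor mapping", {
  set.seed(25)
  gt <- generate_implant(phantom_spec(seed = 31))
  reg2 <- register_reference_sensor(gt$reference_pose, gt$calibration)
  emt <- do.call(rbind, lapply(gt$needles, `[[`, "dwells_emt"))
  dic <- do.call(rbind, lapply(gt$needles, `[[`, "dwells_dicom"))
  reg1 <- register_point_correspondence(emt, dic)
  p <- rand_points(50)
  expect_lt(max(abs(rigid_apply(reg1$transform, p) -
                      rigid_apply(reg2$transform, p))), 1e-6)
})
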