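test_that("straight protocol needle: 11 points at 5 mm cover 50 mm and
           dwells land on the measurement points", {
  pts <- straight_series_points()
  sp <- fit_needle_spline(pts, channel_id = 1)
  expect_equal(sp$total_arc_length, 50, tolerance = 1e-9)
  dw <- derive_dwells(sp, step = 5, tip_offset = 0)
  expect_equal(nrow(dw$positions), 11)
  expect_lt(max(abs(dw$positions - pts)), 1e-9)
})

test_that("two points degenerate to the straight segment", {
  sp <- fit_needle_spline(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(sp$total_arc_length, 5, tolerance = 1e-12)
  mid <- spline_point_at_arc(sp, 2.5)
  expect_equal(as.numeric(mid), c(1.5, 2, 0), tolerance = 1e-9)
})

test_that("duplicate consecutive points are a hard error", {
  expect_error(fit_needle_spline(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 5))),
               "zero chord")
})

test_that("circle-arc needle: spline arc length matches the closed form", {
  R <- 100; chord <- 5
  theta <- 2 * asin(chord / 2 / R)
  angles <- theta * (0:10)
  pts <- cbind(R * sin(angles), R * (1 - cos(angles)), 0)
  sp <- fit_needle_spline(pts)
  analytic <- R * theta * 10         # true circular arc over 10 segments
  expect_lt(abs(sp$total_arc_length - analytic), 0.01)
})

test_that("control-point resampling hits the requested arc grid", {
  pts <- straight_series_points()
  sp <- fit_needle_spline(pts)
  cp <- resample_control_points(sp, 5)
  expect_equal(nrow(cp), 11)
  expect_equal(diff(cp[, 3]), rep(-5, 10), tolerance = 1e-9)
  # spacing beyond the path: exactly the two endpoints
  cp2 <- resample_control_points(sp, 60)
  expect_equal(nrow(cp2), 2)
  expect_equal(as.numeric(cp2[, 3]), c(55, 5), tolerance = 1e-9)
  # curved path: adjacent separations equal the spacing by dense polyline
  set.seed(31)
  bow <- straight_series_points()
  bow[, 1] <- bow[, 1] + 2 * ((55 - bow[, 3]) / 50)^2
  spb <- fit_needle_spline(bow)
  cpb <- resample_control_points(spb, 5)
  tt <- seq(spb$u[1], spb$u[length(spb$u)], length.out = 200001)
  dense <- spline_eval(spb, tt)
  cum <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  arcs <- vapply(seq_len(nrow(cpb)), function(i) {
    j <- which.min(rowSums(sweep(dense, 2, cpb[i, ])^2))
    cum[j]
  }, numeric(1))
  expect_lt(max(abs(diff(arcs[1:(nrow(cpb) - 1)]) - 5)), 1e-3)
})

test_that("dwell derivation follows the arc grid and its preconditions", {
  pts <- straight_series_points()
  sp <- fit_needle_spline(pts)
  d1 <- derive_dwells(sp, step = 5, tip_offset = 2.5)
  expect_equal(nrow(d1$positions), 10)
  expect_equal(d1$arc_offsets[1], 2.5)
  expect_equal(as.numeric(d1$positions[1, 3]), 52.5, tolerance = 1e-9)
  expect_error(derive_dwells(sp, step = 5, tip_offset = 60), "beyond")
  expect_error(derive_dwells(sp, step = -1), "> 0")
})

test_that("free length matches analytic and dense-polyline constructions", {
  # perpendicular needle, 30 mm beyond the plane
  pts <- cbind(0, 0, seq(30, -30, by = -5))
  sp <- fit_needle_spline(pts)
  expect_equal(free_length(sp, 0), 30, tolerance = 1e-6)
  # 45 degrees: plane-to-end arc = dz / cos(45)
  pts45 <- cbind(5 * (0:12), 0, seq(30, -30, by = -5))
  sp45 <- fit_needle_spline(pts45)
  expect_equal(free_length(sp45, 0), 30 * sqrt(2), tolerance = 1e-6)
  # curved needle vs dense polyline
  bow <- cbind(2 * ((30 - seq(30, -30, by = -5)) / 60)^2, 0,
               seq(30, -30, by = -5))
  spb <- fit_needle_spline(bow)
  tt <- seq(spb$u[1], spb$u[length(spb$u)], length.out = 400001)
  dense <- spline_eval(spb, tt)
  seg <- sqrt(rowSums(diff(dense)^2))
  cum <- c(0, cumsum(seg))
  cross <- which(dense[-1, 3] * dense[-nrow(dense), 3] <= 0)[1]
  expect_lt(abs(free_length(spb, 0) - (cum[length(cum)] - cum[cross])),
            1e-3)
  expect_error(free_length(sp, 100), "does not cross")
})

test_that("reconstruction is equivariant under rigid transforms", {
  set.seed(32)
  bow <- straight_series_points()
  bow[, 1] <- bow[, 1] + 1.5 * ((55 - bow[, 3]) / 50)^2
  s <- measurement_series(1, bow, 5)
  tr <- rand_rigid()
  reg <- structure(list(transform = tr, rms_residual = 0,
                        method = "reference_sensor"),
                   class = "registration_result")
  a <- reconstruct_needle(transform_series(s, reg))
  b <- reconstruct_needle(s)
  expect_lt(max(abs(a$dwells$positions -
                      rigid_apply(tr, b$dwells$positions))), 1e-6)
  expect_lt(max(abs(a$control_points -
                      rigid_apply(tr, b$control_points))), 1e-6)
})

test_that("quadratic bows are interpolated within 0.05 mm between samples", {
  for (defl in c(1, 2, 3)) {
    z <- seq(55, 5, by = -5)
    truth_fun <- function(zz) defl * ((55 - zz) / 50)^2
    sp <- fit_needle_spline(cbind(truth_fun(z), 0, z))
    zz <- seq(55, 5, length.out = 401)
    # evaluate the spline at the parameters whose z matches zz
    tt <- vapply(zz, function(zv)
      uniroot(function(t) sp$fz(t) - zv, range(sp$u), tol = 1e-12)$root,
      numeric(1))
    pts <- spline_eval(sp, tt)
    expect_lt(max(abs(pts[, 1] - truth_fun(zz))), 0.05)
  }
})

test_that("reconstruction TSV round trips", {
  pts <- straight_series_points()
  nd <- reconstruct_needle(measurement_series(2, pts, 5))
  path <- tempfile(fileext = ".tsv")
  write_reconstruction_tsv(list(nd), path)
  df <- read_reconstruction_tsv(path)
  expect_setequal(unique(df$kind), c("control", "dwell"))
  dw <- df[df$kind == "dwell", ]
  expect_equal(nrow(dw), 11)
  expect_equal(as.numeric(dw$z[1]), 55, tolerance = 1e-9)
})
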