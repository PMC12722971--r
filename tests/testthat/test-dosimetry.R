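test_that("point-source dose follows the inverse-square law with g == 1", {
  src <- unit_g_source()
  grid <- dose_grid(origin = c(10, 0, 0), spacing = 10, dims = c(2, 1, 1),
                    prescription_gy = 8.5)
  d <- compute_dose(list(list(positions = rbind(c(0, 0, 0)), times = 10)),
                    src, grid)
  expect_equal(d$values[1, 1, 1] / d$values[2, 1, 1], 4,
               tolerance = 1e-9)
  # zero dwell times: zero everywhere
  d0 <- compute_dose(list(list(positions = rbind(c(0, 0, 0)), times = 0)),
                     src, grid)
  expect_true(all(d0$values == 0))
  # superposition of two symmetric dwells
  d2 <- compute_dose(list(list(positions = rbind(c(-10, 0, 0), c(30, 0, 0)),
                               times = c(10, 10))), src, grid)
  d1 <- compute_dose(list(list(positions = rbind(c(-10, 0, 0)),
                               times = 10)), src, grid)
  expect_equal(d2$values[1, 1, 1], 2 * d1$values[1, 1, 1],
               tolerance = 1e-9)
  expect_error(dose_grid(c(0, 0, 0), 1, c(0, 5, 5), 8.5), "zero-extent")
  expect_error(compute_dose(list(list(positions = rbind(c(0, 0, 0)),
                                      times = -1)), src, grid),
               "negative")
})

test_that("dose is linear in dwell time", {
  set.seed(41)
  src <- source_model()
  grid <- dose_grid(c(-20, -20, -20), 4, c(11, 11, 11), 8.5)
  dw <- list(list(positions = rand_points(5, 15), times = runif(5, 2, 20)))
  g1 <- compute_dose(dw, src, grid)
  dw2 <- list(list(positions = dw[[1]]$positions,
                   times = 2 * dw[[1]]$times))
  g2 <- compute_dose(dw2, src, grid)
  expect_equal(g2$values, 2 * g1$values, tolerance = 1e-12)
})

test_that("DVH metrics on a uniform dose are the uniform dose", {
  grid <- dose_grid(c(0, 0, 0), 1, c(30, 30, 10), prescription_gy = 10)
  grid$values[] <- 10
  square <- list(name = "box", number = 1, role = "other",
                 contours = lapply(seq(0, 9), function(z)
                   list(z = z, xy = rbind(c(2, 2), c(27, 2), c(27, 27),
                                          c(2, 27)))))
  m <- dvh_metrics(grid, square)
  expect_equal(m$v100_pct, 100)
  expect_equal(unname(m$d_gy), rep(10, 3))
  grid$values[] <- 9.99
  expect_equal(dvh_metrics(grid, square)$v100_pct, 0)
})

test_that("hot-spot metrics are monotone in volume on random plans", {
  set.seed(42)
  src <- source_model()
  grid <- dose_grid(c(-25, -25, -25), 2, c(26, 26, 26), 8.5)
  ball <- list(name = "ball", number = 1, role = "other",
               contours = lapply(seq(-15, 15, by = 2), function(z) {
                 r <- sqrt(max(1, 15^2 - z^2))
                 th <- seq(0, 2 * pi, length.out = 33)[-33]
                 list(z = z, xy = cbind(r * cos(th), r * sin(th)))
               }))
  mask <- rasterize_structure(ball, grid)
  for (i in 1:5) {
    dw <- list(list(positions = rand_points(8, 12), times = runif(8, 1, 20)))
    m <- dvh_metrics(compute_dose(dw, src, grid), mask)
    expect_gte(m$d_gy[["D0.1cm3"]], m$d_gy[["D1cm3"]])
    expect_gte(m$d_gy[["D1cm3"]], m$d_gy[["D2cm3"]])
    expect_gte(m$v100_pct, 0); expect_lte(m$v100_pct, 100)
  }
  expect_error(dvh_metrics(compute_dose(
    list(list(positions = rbind(c(0, 0, 0)), times = 1)), src, grid),
    list(name = "far", number = 9, role = "other",
         contours = list(list(z = 500, xy = rbind(c(0, 0), c(1, 0),
                                                  c(0, 1)))))),
    "zero voxels")
})

test_that("spherical V-threshold matches the closed form", {
  # g == 1, phi == 1 point source at the center of a 12 mm sphere:
  # dose >= D exactly inside radius r_t, so V = (r_t / R)^3
  src <- unit_g_source(Lambda = 1, phi_an = 1)
  t_s <- 48
  presc <- 8.5
  k <- src$sk * t_s / 3600 / 100          # Gy at 1 cm
  r_t_mm <- 10 * sqrt(k / presc)
  expect_true(r_t_mm > 6 && r_t_mm < 10)
  h <- 1
  grid <- dose_grid(c(-14, -14, -14), h, c(29, 29, 29), presc)
  R <- 12
  sphere <- list(name = "shell", number = 1, role = "other",
                 contours = lapply(seq(-11.5, 11.5, by = h), function(z) {
                   r <- sqrt(max(0.5, R^2 - z^2))
                   th <- seq(0, 2 * pi, length.out = 97)[-97]
                   list(z = z, xy = cbind(r * cos(th), r * sin(th)))
                 }))
  d <- compute_dose(list(list(positions = rbind(c(0, 0, 0)),
                              times = t_s)), src, grid)
  v <- dvh_metrics(d, sphere)$v100_pct
  analytic <- 100 * (r_t_mm / R)^3
  expect_lt(abs(v - analytic) / analytic, 0.05)  # 1 mm grid; 0.5 mm in
                                                 # the acceptance suite
})

test_that("metric differences are zero for identical plans and match an
           independent DVH recomputation", {
  set.seed(44)
  gt <- generate_implant(phantom_spec(seed = 44))
  ap <- generate_anatomy_and_plan(gt, seed = 44)
  src <- source_model()
  grid <- default_grid_for(ap$structs, spacing = 3,
                           prescription_gy = ap$prescription_gy)
  dw <- plan_dwells(ap$plan)
  d0 <- metric_difference(dw, dw, ap$structs, src, grid)
  expect_true(all(abs(d0$delta) < 1e-12))
  # independent oracle: sorted-voxel DVH recomputation
  shifted <- lapply(dw, function(x) {
    x$dwells$positions[, 3] <- x$dwells$positions[, 3] + 3; x
  })
  diffs <- metric_difference(dw, shifted, ap$structs, src, grid)
  ga <- compute_dose(dw, src, grid)
  gb <- compute_dose(shifted, src, grid)
  tgt <- ap$structs$structures$Prostate
  mask <- rasterize_structure(tgt, grid)
  ora_v100 <- function(gr) 100 * mean(gr$values[mask] >= gr$prescription_gy)
  row <- diffs[diffs$structure == "Prostate" & diffs$metric == "V100", ]
  expect_equal(row$delta, ora_v100(ga) - ora_v100(gb), tolerance = 1e-9)
  ora_dx <- function(gr, vol) {
    ds <- sort(gr$values[mask], decreasing = TRUE)
    vv <- (gr$spacing / 10)^3
    cum <- seq_along(ds) * vv
    i <- findInterval(vol, cum)
    w <- (vol - cum[i]) / vv
    ds[i] * (1 - w) + ds[i + 1] * w
  }
  row2 <- diffs[diffs$structure == "Prostate" & diffs$metric == "D2cm3", ]
  expect_equal(row2$delta,
               100 * (ora_dx(ga, 2) - ora_dx(gb, 2)) / grid$prescription_gy,
               tolerance = 1e-9)
})
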