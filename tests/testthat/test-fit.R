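test_that("unit conversion follows pixel size, tilt factor and frame interval", {
  expect_equal(convert_units(1, 6 / 4, 1, 208 / 69000 + 0.002), 299.2,
               tolerance = 1e-3)
  expect_equal(convert_units(0, 1.5, 1, 0.005), 0)
  d_t <- distortion_factors(1.45, 5)$transverse
  expect_equal(convert_units(2, 1.5, d_t, 0.01),
               convert_units(2, 1.5, 1, 0.01) * d_t)
  expect_error(convert_units(1, NULL, 1, 0.01),
               class = "octflow_error_config")
})

test_that("constant-mode velocities average absolute sweep speeds", {
  grid <- structure(list(n_row = 2L, n_col = 2L, depth_um = c(50, 100)),
                    class = "roi_grid")
  # forward sweep +v, backward sweep -v: speed |v|, sd 0
  field <- tibble::tibble(
    k = rep(1:2, 4), i = rep(c(1L, 2L), each = 4),
    j = rep(rep(1:2, each = 2), 2),
    dk = 2L, xshift = rep(c(8, -8), 4), zshift = 0L, rho = 1,
    sweep = rep(c(1L, 2L), 4), t_mid = 0.1)
  prof <- velocities_constant(field, grid, 1.5, 1, 0.027)
  expect_equal(prof$speed_um_s, rep(4 * 1.5 / 0.027, 2))
  expect_equal(prof$sd_um_s, c(0, 0))
  expect_equal(prof$depth_um, c(50, 100))
  expect_true(all(prof$speed_um_s >= 0))
})

test_that("sinusoid fitting recovers parameters and folds negative amplitude", {
  t <- seq(0, 2, by = 0.004)
  f1 <- fit_sinusoid(t, 10 * cos(2 * pi * 3 * t), f0 = 3)
  expect_equal(f1$amplitude, 10, tolerance = 1e-8)
  expect_equal(f1$frequency, 3, tolerance = 1e-8)
  expect_equal(f1$phase, 0, tolerance = 1e-8)
  f2 <- fit_sinusoid(t, -10 * cos(2 * pi * 3 * t), f0 = 3)
  expect_equal(f2$amplitude, 10, tolerance = 1e-8)
  expect_equal(abs(f2$phase_rel_deg), 180, tolerance = 1e-6)
  # self-consistency on its own model values
  f3 <- fit_sinusoid(t, 4.7 * cos(2 * pi * 5.2 * t + 0.9), f0 = 5)
  expect_equal(f3$amplitude, 4.7, tolerance = 1e-8)
  expect_equal(f3$frequency, 5.2, tolerance = 1e-8)
  expect_equal(f3$phase, 0.9, tolerance = 1e-8)
  # noisy recovery within 3 standard errors
  withr::with_seed(99, {
    v <- 10 * cos(2 * pi * 3 * t) + stats::rnorm(length(t), 0, 0.5)
  })
  f4 <- fit_sinusoid(t, v, f0 = 3)
  expect_lt(abs(f4$amplitude - 10), 3 * f4$amplitude_se)
  expect_lt(abs(f4$frequency - 3), 3 * f4$frequency_se)
  # too little data is an explicit fit error
  expect_error(fit_sinusoid(c(0, 0.01, 0.02), c(1, 2, 3), f0 = 3),
               class = "octflow_error_fit")
})

test_that("weighted sinusoid fit uses inverse-variance weights", {
  withr::with_seed(4, {
    t <- seq(0, 1.5, by = 0.005)
    truth <- 8 * cos(2 * pi * 4 * t + 0.3)
    sd <- rep(c(0.1, 2), length.out = length(t))
    v <- truth + stats::rnorm(length(t), 0, sd)
  })
  fw <- fit_sinusoid(t, v, sd = sd, f0 = 4)
  fu <- fit_sinusoid(t, v, f0 = 4)
  expect_lt(abs(fw$amplitude - 8), abs(fu$amplitude - 8) + 0.05)
  expect_lt(abs(fw$amplitude - 8), 3 * fw$amplitude_se)
})

test_that("shear-rate regression recovers exact and weighted slopes", {
  z <- c(30, 60, 90, 120, 150, 180)
  f1 <- suppressWarnings(fit_shear_rate(z, 0.21 * z, theory = 0.21))
  expect_equal(f1$shear_rate, 0.21, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)
  expect_equal(f1$intercept, 0, tolerance = 1e-9)
  # equal weights reduce to ordinary least squares
  withr::with_seed(12, v <- 0.2 * z + stats::rnorm(6, 0, 1))
  fw <- fit_shear_rate(z, v, sigma = rep(2, 6))
  ols <- stats::lm(v ~ z)
  expect_equal(fw$shear_rate, unname(stats::coef(ols)[2]))
  expect_equal(fw$r_squared, summary(ols)$r.squared)
  # zero/NA sigmas get the median weight rather than infinite weight
  fmix <- fit_shear_rate(z, v, sigma = c(0, 2, 2, NA, 2, 2))
  expect_true(is.finite(fmix$shear_rate))
  expect_error(fit_shear_rate(z[1:2], v[1:2]), class = "octflow_error_fit")
  # broom-style accessors
  expect_equal(glance(f1)$shear_rate, 0.21, tolerance = 1e-12)
  expect_equal(nrow(tidy(f1)), 2)
})
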