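test_that("Couette velocity honours the no-slip boundaries and is linear in depth", {
  gm <- chamber_geometry(292, 0, 1.45)
  tri <- driving_waveform("triangle", 0.5, plate_speed = 60,
                          mechanical_delay = 0)
  # upswing of the first quarter period
  expect_equal(couette_velocity(0, 0.1, tri, gm), 0)
  expect_equal(couette_velocity(292, 0.1, tri, gm), 60)
  expect_equal(couette_velocity(146, 0.1, tri, gm), 30)
  # downswing reverses the sign
  expect_equal(couette_velocity(292, 1, tri, gm), -60)
  sin_wf <- driving_waveform("sinusoid", 10, peak_speed = 754, phase = 0,
                             mechanical_delay = 0)
  expect_equal(couette_velocity(150, 0, sin_wf,
                                chamber_geometry(150, 0, 1.45)), 754)
  # exact linearity in z at arbitrary times
  gm2 <- chamber_geometry(200)
  for (t in c(0.013, 0.4, 1.7)) {
    z <- seq(0, 200, by = 12.5)
    v <- couette_velocity(z, t, sin_wf, gm2)
    expect_equal(v, (z / 200) * couette_velocity(200, t, sin_wf, gm2))
  }
  expect_error(couette_velocity(-1, 0, tri, gm),
               class = "octflow_error_domain")
  expect_error(couette_velocity(293, 0, tri, gm),
               class = "octflow_error_domain")
})

test_that("shear rates match the chamber operating envelope", {
  expect_equal(round(shear_rate_constant(60, 292), 2), 0.21)
  expect_equal(shear_rate_constant(60, 300), 0.20)
  expect_equal(shear_rate_constant(0, 300), 0)
  expect_equal(round(shear_rate_amplitude(pi * 10 * 24, 150), 1), 5.0)
  expect_equal(round(shear_rate_amplitude(pi * 10 * 100, 80)), 39)
  expect_equal(shear_rate_amplitude(0, 80), 0)
  expect_error(shear_rate_constant(60, 0), class = "octflow_error_domain")
  expect_error(shear_rate_amplitude(60, -1), class = "octflow_error_domain")
})

test_that("sinusoid peak speed and triangle strain reproduce the printed envelope", {
  expect_equal(signif(peak_speed_sinusoid(10, 24), 2), 750)
  expect_equal(signif(peak_speed_sinusoid(3, 18), 2), 170)
  expect_equal(peak_speed_sinusoid(0, 24), 0)
  expect_error(peak_speed_sinusoid(-1, 24), class = "octflow_error_domain")
  expect_equal(peak_to_peak_strain_triangle(60, 0.5, 300), 0.20)
  expect_equal(round(peak_to_peak_strain_triangle(5, 0.5, 300), 3), 0.017)
  expect_equal(peak_to_peak_strain_triangle(0, 0.5, 300), 0)
  expect_error(peak_to_peak_strain_triangle(60, 0, 300),
               class = "octflow_error_domain")
})

test_that("viscous transient time is H^2 rho / mu and scales quadratically", {
  fl <- fluid_properties(294, 1185)
  tau <- transient_time(300, fl)
  expect_lt(tau, 1e-3)  # negligible for the experimental fluids
  expect_equal(transient_time(100, fluid_properties(1, 1000)), 0.01)
  expect_equal(transient_time(0, fl), 0)
  expect_equal(transient_time(200, fl), 4 * transient_time(100, fl))
})

test_that("Arago-Biot index interpolates the component indices by weight", {
  expect_equal(arago_biot_index(1, 0), 1.340)
  expect_equal(arago_biot_index(0, 1), 1.465)
  expect_equal(arago_biot_index(0.5, 0.5), 1.4025)
  expect_error(arago_biot_index(0.5, 0.4),
               class = "octflow_error_validation")
})

test_that("plate position integrates the plate velocity", {
  tri <- driving_waveform("triangle", 0.5, plate_speed = 60)
  # peak-to-peak travel Vx0 / (2 f)
  tt <- seq(0, 4, by = 1e-3)
  expect_equal(diff(range(plate_position(tt, tri))), 60, tolerance = 1e-3)
  sin_wf <- driving_waveform("sinusoid", 10, peak_to_peak = 24)
  expect_equal(plate_position(sin_wf$mechanical_delay, sin_wf), 0)
  # numerical derivative matches couette_velocity at z = H
  gm <- chamber_geometry(150)
  dt <- 1e-6
  turns <- c()
  for (wf in list(tri, sin_wf)) {
    ts <- seq(0.05, 1.9, by = 0.037)
    if (wf$kind == "triangle") {
      # stay away from instantaneous turnarounds
      Tp <- 1 / wf$frequency
      ph <- ((ts - wf$mechanical_delay) * wf$frequency) %% 1
      ts <- ts[pmin(abs(ph - 0.25), abs(ph - 0.75)) > 0.01]
    }
    num <- (plate_position(ts + dt, wf) - plate_position(ts - dt, wf)) /
      (2 * dt)
    v <- couette_velocity(150, ts, wf, gm)
    expect_equal(num, v, tolerance = 1e-4)
  }
})

test_that("waveform kinematics compose: amplitude over H equals pi f D / H", {
  for (f in c(1, 3, 10)) {
    for (dpp in c(10, 24, 100)) {
      for (H in c(80, 150, 500)) {
        expect_equal(shear_rate_amplitude(peak_speed_sinusoid(f, dpp), H),
                     pi * f * dpp / H)
      }
    }
  }
})

test_that("operating point table collects the analytic quantities", {
  op <- operating_point(driving_waveform("sinusoid", 10, peak_to_peak = 24),
                        chamber_geometry(150),
                        fluid_properties(347, 1180))
  expect_s3_class(op, "tbl_df")
  expect_equal(op$shear_rate_s1, pi * 10 * 24 / 150)
  expect_lt(op$transient_time_s, 1e-3)
  expect_lt(op$reynolds, 1e-2)
})
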