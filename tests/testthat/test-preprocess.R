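test_that("distortion factors have the correct limits and monotonicity", {
  d <- distortion_factors(1, 0)
  expect_equal(d$axial, 1)
  expect_equal(d$transverse, 1)
  d2 <- distortion_factors(1.45, 0)
  expect_equal(d2$axial, 1 / 1.45)
  a <- 5 * pi / 180
  d3 <- distortion_factors(1.45, 5)
  expect_equal(d3$axial, sqrt(1.45^2 - sin(a)^2) / 1.45^2)
  expect_equal(d3$transverse, 1 / cos(a), tolerance = 1e-12)
  expect_equal(round(d3$transverse, 4), 1.0038)
  # axial decreases with n, transverse increases with |alpha|
  ns <- seq(1, 1.6, by = 0.1)
  expect_true(all(diff(vapply(ns, function(n)
    distortion_factors(n, 3)$axial, numeric(1))) < 0))
  as <- seq(0, 20, by = 2)
  expect_true(all(diff(vapply(as, function(al)
    distortion_factors(1.45, al)$transverse, numeric(1))) > 0))
})

test_that("start-up discard drops exactly the first 30 ms of frames", {
  mk <- function(dt, n) {
    fr <- array(stats::runif(8 * 10 * n), c(8, 10, n))
    st <- oct_stack(fr, a_line_rate = 10 / dt, dead_time = 0,
                    pixel_size_x = 6, pixel_size_z = 2)
    st
  }
  st5 <- mk(0.005, 20)
  expect_equal(n_frames(discard_startup(st5)), 14)   # 6 frames dropped
  st27 <- mk(0.027, 10)
  expect_equal(n_frames(discard_startup(st27)), 8)   # 2 frames dropped
  expect_equal(n_frames(discard_startup(st27, 0)), 10)  # override: identity
  expect_error(discard_startup(mk(0.005, 3)),
               class = "octflow_error_invalid_stack")
  # timestamps stay absolute
  expect_equal(discard_startup(st5)$time[1], 0.03)
})

test_that("lateral upsampling interpolates and rescales pixel metadata", {
  fr <- array(stats::runif(10 * 250 * 2), c(10, 250, 2))
  st <- oct_stack(fr, 1e4, 2e-3, pixel_size_x = 6, pixel_size_z = 2)
  up <- upsample_lateral(st, 4)
  expect_equal(dim(up$frames), c(10, 1000, 2))
  expect_equal(up$pixel_size_x, 1.5)
  expect_equal(up$upsample, 4L)
  expect_identical(upsample_lateral(st, 1)$frames, st$frames)
  # cubic interpolation reproduces a linear ramp away from the edges
  ramp <- array(rep(seq_len(50), each = 4), c(4, 50, 1))
  str <- oct_stack(ramp, 1e4, 2e-3, 6, 2)
  upr <- upsample_lateral(str, 4)
  xin <- seq_len(50)
  xout <- (seq_len(200) - 0.5) / 4 + 0.5
  inner <- xout > 2 & xout < 49
  expect_equal(upr$frames[1, inner, 1], xout[inner], tolerance = 1e-9)
  # a blob centered between two native columns gains a unique argmax
  g <- exp(-(seq_len(50) - 25.5)^2 / 4)
  blob <- array(rep(g, each = 4), c(4, 50, 1))
  stb <- upsample_lateral(oct_stack(blob, 1e4, 2e-3, 6, 2), 4)
  row <- stb$frames[1, , 1]
  expect_equal(sum(row == max(row)), 1)
})

test_that("tilt detection and flattening recover the simulated geometry", {
  # (n, alpha, H) grid: recovered tilt within 0.1 deg, H within 1 axial px
  for (cfg in list(c(1.34, 0, 150), c(1.45, 2, 150),
                   c(1.45, 0, 292), c(1.34, 2, 292))) {
    n <- cfg[1]; alpha <- cfg[2]; H <- cfg[3]
    wf <- driving_waveform("sinusoid", 10, peak_to_peak = 24)
    geom <- chamber_geometry(H, alpha, n)
    scene <- scene_config(seed = 5, noise_std = 0.01)
    d_ax <- distortion_factors(n, alpha)$axial
    n_z <- preset_image_height(scene, H, n, alpha, 5.77, 2, 208)
    acq <- acquisition_params(69000, 208, 0.002, 5.77, 2,
                              n_frames = 3, n_z = n_z)
    st <- generate_stack(scene, acq, wf, geom)
    stu <- upsample_lateral(st, 4)
    plates <- detect_plates(stu)
    expect_equal(plates$angle_deg[plates$plate == "top"], alpha,
                 tolerance = 0.105)
    flat <- flatten_tilt(stu, plates, n = n)
    expect_lt(abs(flat$measured_H - H), 2 * d_ax + 1e-9)  # 1 axial px
    # flattening is idempotent: re-detection finds a horizontal plate
    re <- detect_plates(flat)
    expect_lt(abs(re$angle_deg[re$plate == "top"]), 0.1)
  }
})

test_that("non-parallel plates are rejected", {
  st <- small_triangle_stack()
  stu <- upsample_lateral(discard_startup(st), 4)
  slope2deg <- tan(2 * pi / 180) * stu$pixel_size_x / stu$pixel_size_z
  override <- tibble::tibble(plate = c("top", "bottom"),
                             slope = c(0, slope2deg),
                             intercept = c(20, 230))
  plates <- detect_plates(stu, override = override)
  expect_error(flatten_tilt(stu, plates, n = 1.45),
               class = "octflow_error_not_parallel")
})
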