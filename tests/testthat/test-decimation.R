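test_that("turnaround padding masks frames near triangle peaks and valleys", {
  wf <- driving_waveform("triangle", 0.5, plate_speed = 60)
  dt <- 0.027
  time <- (0:148) * dt  # ~4 s, covers several turnarounds
  keep <- pad_turnarounds(time, wf, dt)
  turns <- seq(wf$mechanical_delay + 0.5, max(time), by = 1)
  for (tt in turns) {
    n_masked <- sum(!keep[abs(time - tt) < 0.5])
    expect_gte(n_masked, 4)  # 2 each side (plus the turnaround frame)
    expect_lte(n_masked, 5)
  }
  # every masked frame is within 2 intervals of some turnaround
  masked_t <- time[!keep]
  expect_true(all(vapply(masked_t, function(x)
    min(abs(x - turns)) <= 2 * dt + 1e-9, logical(1))))
  # sinusoid: no padding
  sw <- driving_waveform("sinusoid", 10, peak_to_peak = 24)
  expect_true(all(pad_turnarounds(time, sw, dt)))
})

test_that("sweep indexing segments the triangle drive at its turnarounds", {
  wf <- driving_waveform("triangle", 1, plate_speed = 60,
                         mechanical_delay = 0)
  # quarter period 0.25 s: sweep changes at 0.25, 0.75, 1.25, ...
  expect_equal(octflow:::sweep_index(c(0.1, 0.3, 0.8, 1.3), wf),
               c(1L, 2L, 3L, 4L))
})

test_that("constant-mode decimation targets ~p_target pixels per pair", {
  st <- small_triangle_stack(noise_std = 0.02)
  stu <- upsample_lateral(discard_startup(st), 4)
  flat <- flatten_tilt(stu, n = 1.45)
  grid <- partition_grid(flat)
  thr <- threshold_rows(flat, grid)
  val <- build_validity(flat, grid, thr)
  wf <- st$meta$waveform
  plan <- plan_decimation_constant(flat, grid, thr, val, wf, p_target = 8)
  expect_s3_class(plan, "decimation_plan")
  # decimation decreases (weakly) with depth: slow rows get larger dk
  expect_true(all(diff(plan$dk) <= 0))
  expect_true(all(plan$dk >= 1))
  # bottom-row estimate close to the theoretical px/frame displacement
  d_theory <- 60 * (grid$depth_um[grid$n_row] / flat$measured_H) *
    frame_interval(flat) / flat$pixel_size_x
  expect_lt(abs(plan$d_bottom - d_theory) / d_theory, 0.25)
  # measured velocity per frame is independent of p_target
  keep <- pad_turnarounds(flat$time, wf, frame_interval(flat))
  f1 <- measure_displacements(flat, grid, thr, val, plan, wf, keep)
  plan2 <- plan_decimation_constant(flat, grid, thr, val, wf, p_target = 16)
  f2 <- measure_displacements(flat, grid, thr, val, plan2, wf, keep)
  v1 <- mean(abs(f1$xshift[f1$i == grid$n_row] / f1$dk[f1$i == grid$n_row]))
  v2 <- mean(abs(f2$xshift[f2$i == grid$n_row] / f2$dk[f2$i == grid$n_row]))
  expect_lt(abs(v1 - v2), 0.5)
})

test_that("sinusoidal decimation caps at a quarter period and tracks |cos|", {
  st <- small_sinusoid_stack(noise_std = 0.02, frequency = 10)
  stu <- upsample_lateral(discard_startup(st), 4)
  flat <- flatten_tilt(stu, n = 1.45)
  grid <- partition_grid(flat)
  thr <- threshold_rows(flat, grid)
  val <- build_validity(flat, grid, thr)
  wf <- st$meta$waveform
  plan <- plan_decimation_sinusoidal(flat, grid, thr, val, wf)
  cap_expect <- floor((1 / 10) / (4 * frame_interval(flat)))
  expect_equal(plan$cap, cap_expect)
  expect_true(all(plan$dk >= 1 & plan$dk <= plan$cap))
  # top (slow) rows are decimated at least as hard as the bottom row
  expect_true(all(plan$dk[1, ] >= plan$dk[grid$n_row, ]))
  # a drive faster than a quarter of the frame rate is rejected
  fast <- driving_waveform("sinusoid", 60, peak_to_peak = 24)
  expect_error(
    plan_decimation_sinusoidal(flat, grid, thr, val, fast),
    class = "octflow_error_frame_rate")
})
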