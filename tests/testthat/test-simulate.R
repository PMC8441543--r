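test_that("advection follows the integrated Couette flow", {
  gm <- chamber_geometry(300, 0, 1.45)
  tri <- driving_waveform("triangle", 0.5, plate_speed = 60,
                          mechanical_delay = 0)
  pos <- tibble::tibble(particle = 1:3, x = c(100, 100, 100),
                        z = c(0, 150, 300))
  # interval inside the first upswing: bottom particle moves Vx0 * dt
  out <- advect_particles(pos, tri, gm, 0.1, 0.2)
  expect_equal(out$x, c(100, 103, 106))
  expect_equal(out$z, pos$z)
  # top-plate particle never moves
  out2 <- advect_particles(pos, tri, gm, 0, 1.73)
  expect_equal(out2$x[1], 100)
  # sinusoid: zero net displacement over a full period
  sw <- driving_waveform("sinusoid", 5, peak_to_peak = 24,
                         mechanical_delay = 0)
  out3 <- advect_particles(pos, sw, gm, 0.4, 0.6)
  expect_equal(out3$x, pos$x, tolerance = 1e-9)
})

test_that("rendered frames put plates and particles where expected", {
  gm <- chamber_geometry(150, 0, 1.45)
  wf <- driving_waveform("sinusoid", 10, peak_to_peak = 24)
  scene <- scene_config(noise_std = 0, top_plate_row = 15)
  acq <- acquisition_params(69000, 208, 0.002, 5.77, 2,
                            n_frames = 1, n_z = 140)
  d_ax <- distortion_factors(1.45, 0)$axial
  # no particles: nothing but the two plate ridges
  img0 <- render_frame(tibble::tibble(x = numeric(), z = numeric()),
                       scene, acq, gm, wf, 0)
  off <- img0[30:100, ]  # region away from both plates
  expect_equal(max(off), 0)
  # one particle: off-plate argmax at its refraction-scaled pixel position
  pos <- tibble::tibble(x = 600, z = 75)
  img1 <- render_frame(pos, scene, acq, gm, wf, 0)
  blob <- img1[30:100, ]
  idx <- which(blob == max(blob), arr.ind = TRUE)
  expect_lt(abs(idx[[1, 1]] + 29 - (15 + 75 / (2 * d_ax))), 1)
  expect_lt(abs(idx[[1, 2]] - (600 / 5.77 + 1)), 1)
  # deeper sensitivity roll-off dims deep blobs monotonically
  sc2 <- scene_config(noise_std = 0, top_plate_row = 15,
                      rolloff_decay_length = 1200)
  img2 <- render_frame(pos, sc2, acq, gm, wf, 0)
  expect_gt(max(img2[30:100, ]), max(blob))
})

test_that("stack generation is deterministic and carries exact ground truth", {
  p <- preset_sinusoid(frequency = 10, n_cycles = 1,
                       scene = scene_config(seed = 77))
  s1 <- generate_stack(p$scene, p$acq, p$waveform, p$geom)
  s2 <- generate_stack(p$scene, p$acq, p$waveform, p$geom)
  expect_identical(s1$frames, s2$frames)
  expect_equal(s1$meta$ground_truth$shear_rate, pi * 10 * 24 / 150)
  # particle count conserved in every frame
  counts <- table(s1$meta$ground_truth$positions$frame)
  expect_true(all(counts == counts[1]))
})

test_that("ground-truth bottom-row motion matches the plate velocity", {
  st <- small_triangle_stack(noise_std = 0.02)
  wf <- st$meta$waveform
  gt <- st$meta$ground_truth$positions
  deep <- gt[gt$z > 0.95 * 292, ]
  p1 <- deep[deep$frame == 20, ]
  p2 <- deep[deep$frame == 21, ]
  dt <- st$time[21] - st$time[20]
  # both frames inside one sweep: displacement = (z/H) Vx0 dt
  dx <- p2$x - p1$x
  expected <- (p1$z / 292) * plate_position(st$time[21], wf) -
    (p1$z / 292) * plate_position(st$time[20], wf)
  expect_equal(dx, expected, tolerance = 1e-6)
})

test_that("summed intensity is stable across frames without noise or tilt", {
  wf <- driving_waveform("sinusoid", 10, peak_to_peak = 24)
  geom <- chamber_geometry(150, 0, 1.45)
  scene <- scene_config(seed = 3, noise_std = 0)
  acq <- acquisition_params(69000, 208, 0.002, 5.77, 2,
                            n_frames = 12, n_z = 144)
  st <- generate_stack(scene, acq, wf, geom)
  sums <- apply(st$frames, 3, sum)
  expect_lt(diff(range(sums)) / mean(sums), 0.01)
})

test_that("TIFF write/read round trip preserves pixels and timing metadata", {
  p <- preset_sinusoid(frequency = 10, n_cycles = 1,
                       scene = scene_config(seed = 9))
  st <- generate_stack(p$scene, p$acq, p$waveform, p$geom)
  path <- file.path(tempdir(), "roundtrip.tiff")
  write_stack(st, path)
  rt <- read_stack(path)
  expect_equal(rt$frames, st$frames)
  expect_equal(rt$time, st$time)
  expect_equal(rt$frame_interval, 208 / 69000 + 0.002)
  expect_equal(rt$meta$waveform$peak_speed, st$meta$waveform$peak_speed)
  # frame-rate bookkeeping matches the acquisition presets
  expect_equal(1 / (250 / 10000 + 0.002), 37, tolerance = 0.01)
  expect_equal(1 / rt$frame_interval, 199, tolerance = 0.01)
  # a missing sidecar is a schema error
  file.remove(sidecar <- paste0(path, ".json"))
  expect_error(read_stack(path), class = "octflow_error_schema")
  file.remove(path)
})
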