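# Brute-force evaluation of the normalized cross-correlation displacement:
# the literal double sum over candidate shifts with explicit index ranges
# (terms outside the window are zero). Independent of the packaged
# implementation; used as the oracle.
ncc_bruteforce <- function(I1, I2, search_x, search_z) {
  m1 <- mean(I1); m2 <- mean(I2)
  n_z <- nrow(I1); n_x <- ncol(I1)
  denom <- sqrt(sum((I1 - m1)^2) * sum((I2 - m2)^2))
  us <- seq(-search_x, search_x)
  vs <- seq(-search_z, search_z)
  grid <- expand.grid(v = vs, u = us)
  grid$rho <- NA_real_
  for (r in seq_len(nrow(grid))) {
    u <- grid$u[r]; v <- grid$v[r]
    xs <- max(1, 1 - u):min(n_x, n_x - u)
    zs <- max(1, 1 - v):min(n_z, n_z - v)
    grid$rho[r] <- sum((I1[zs, xs] - m1) * (I2[zs + v, xs + u] - m2)) / denom
  }
  peak <- max(grid$rho)
  cand <- grid[grid$rho == peak, ]
  cand <- cand[order(abs(cand$u), abs(cand$v), cand$u, cand$v), ]
  list(xshift = cand$u[1], zshift = cand$v[1], rho = peak)
}

# Minimal flattened-stack object for grid/threshold unit tests, bypassing
# the imaging front end.
fake_flat <- function(frames, top_row, bottom_row,
                      pixel_size_x = 1.5, pixel_size_z = 2,
                      upsample = 4L, n = 1.45, alpha = 0) {
  d_ax <- distortion_factors(n, alpha)$axial
  st <- oct_stack(frames, a_line_rate = 1e4, dead_time = 2e-3,
                  pixel_size_x = pixel_size_x, pixel_size_z = pixel_size_z)
  st$upsample <- as.integer(upsample)
  st$top_plate_row <- as.integer(top_row)
  st$bottom_plate_row <- as.integer(bottom_row)
  st$measured_H <- (bottom_row - top_row) * pixel_size_z * d_ax
  st$measured_alpha <- alpha
  st$axial_factor <- d_ax
  class(st) <- c("flattened_stack", class(st))
  st
}

# Shared slow fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A compact 1 Hz triangle-drive stack (2 cycles, ~76 frames) used by the
# unit tests; the acceptance tests use the full experimental presets.
small_triangle_stack <- function(noise_std = 0.02, seed = 42,
                                 tilt_alpha = 1) {
  key <- sprintf("tri_%g_%d_%g", noise_std, seed, tilt_alpha)
  cached(key, {
    wf <- driving_waveform("triangle", frequency = 1, plate_speed = 60)
    geom <- chamber_geometry(292, tilt_alpha, 1.45)
    scene <- scene_config(seed = seed, noise_std = noise_std)
    n_z <- preset_image_height(scene, 292, 1.45, tilt_alpha, 6, 2, 250)
    acq <- acquisition_params(10000, 250, 0.002, 6, 2,
                              n_frames = 78, n_z = n_z)
    generate_stack(scene, acq, wf, geom)
  })
}

small_sinusoid_stack <- function(noise_std = 0.02, seed = 43,
                                 frequency = 10) {
  key <- sprintf("sin_%g_%d_%g", noise_std, seed, frequency)
  cached(key, {
    p <- preset_sinusoid(frequency = frequency,
                         scene = scene_config(seed = seed,
                                              noise_std = noise_std),
                         n_cycles = 4)
    generate_stack(p$scene, p$acq, p$waveform, p$geom)
  })
}
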