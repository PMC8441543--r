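#' Acquisition parameters
#'
#' Timing and sampling of the B-mode acquisition. The frame interval is
#' `a_lines_per_frame / a_line_rate + dead_time`.
#'
#' @param a_line_rate A-line rate in Hz.
#' @param a_lines_per_frame A-lines (columns) per frame.
#' @param dead_time Dead time between frames in seconds (default 2 ms).
#' @param pixel_size_x_free_space Lateral pixel size in micrometers.
#' @param pixel_size_z_free_space Axial (free-space) pixel size in micrometers.
#' @param n_frames Number of frames to generate.
#' @param n_z Image height in pixels.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(a_line_rate, a_lines_per_frame,
                               dead_time = 0.002,
                               pixel_size_x_free_space,
                               pixel_size_z_free_space = 2,
                               n_frames, n_z) {
  vals <- c(a_line_rate, a_lines_per_frame, dead_time,
            pixel_size_x_free_space, pixel_size_z_free_space, n_frames, n_z)
  if (any(vals <= 0) && dead_time != 0) {
    rlang::abort("Acquisition parameters must be positive.",
                 class = "octflow_error_validation")
  }
  structure(
    list(a_line_rate = a_line_rate,
         a_lines_per_frame = as.integer(a_lines_per_frame),
         dead_time = dead_time,
         pixel_size_x_free_space = pixel_size_x_free_space,
         pixel_size_z_free_space = pixel_size_z_free_space,
         n_frames = as.integer(n_frames),
         n_z = as.integer(n_z),
         frame_interval = a_lines_per_frame / a_line_rate + dead_time),
    class = "acquisition_params")
}

#' Synthetic scene parameters
#'
#' Describes the imaged scene for the synthetic generator: tracer particle
#' load, point-spread function, plate rendering, depth roll-off and noise.
#' Defaults mirror the imaging system the analysis targets: 12 um lateral and
#' 3 um axial resolution (in air), ~2 um polystyrene microspheres.
#'
#' @param particles_per_roi Mean number of particles per ROI-sized cell used
#'   by the stratified placement (the tracker expects roughly 1-4).
#' @param particle_diameter Tracer diameter in micrometers (adds in quadrature
#'   to the PSF when rendering).
#' @param psf_lateral_fwhm,psf_axial_fwhm PSF FWHM in micrometers (in air).
#' @param particle_intensity,plate_intensity Peak rendered intensities in
#'   `[0, 1]`.
#' @param rolloff_decay_length Depth sensitivity roll-off 1/e length in
#'   micrometers (applied as `exp(-depth / length)` on intensity).
#' @param noise_std Additive Gaussian noise standard deviation (intensity
#'   units; clipped at zero).
#' @param top_plate_row Apparent row of the top plate at the left edge, px.
#' @param intra_frame_timing If `TRUE` (default) each column is rendered at
#'   its own A-line time, modelling lateral beam scanning of moving particles.
#' @param artifact_streak If `TRUE`, injects a static bright horizontal
#'   streak just below the top plate, emulating an autocorrelation artifact
#'   (exercises the cluster-check rejection path).
#' @param seed Integer seed; fixes the generated stack bit-exactly.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(particles_per_roi = 2,
                         particle_diameter = 2.07,
                         psf_lateral_fwhm = 12,
                         psf_axial_fwhm = 3,
                         particle_intensity = 0.65,
                         plate_intensity = 1,
                         rolloff_decay_length = 600,
                         noise_std = 0.02,
                         top_plate_row = 20,
                         intra_frame_timing = TRUE,
                         artifact_streak = FALSE,
                         seed = 1L) {
  stopifnot(particles_per_roi > 0, psf_lateral_fwhm > 0, psf_axial_fwhm > 0)
  structure(
    list(particles_per_roi = particles_per_roi,
         particle_diameter = particle_diameter,
         psf_lateral_fwhm = psf_lateral_fwhm,
         psf_axial_fwhm = psf_axial_fwhm,
         particle_intensity = particle_intensity,
         plate_intensity = plate_intensity,
         rolloff_decay_length = rolloff_decay_length,
         noise_std = noise_std,
         top_plate_row = top_plate_row,
         intra_frame_timing = intra_frame_timing,
         artifact_streak = artifact_streak,
         seed = as.integer(seed)),
    class = "scene_config")
}

#' Image height needed to contain both plates
#'
#' Rows required to fit the top plate margin, the refraction-scaled plate
#' separation, the tilt drop across the lateral field, and a bottom margin.
#'
#' @param scene A [scene_config()] (for the top plate row).
#' @param H Plate separation (um).
#' @param n Refractive index.
#' @param alpha Tilt (degrees).
#' @param px,pz Pixel sizes (um).
#' @param n_x Lateral pixels.
#' @return Integer pixel height.
#' @export
preset_image_height <- function(scene, H, n, alpha, px, pz, n_x) {
  d_ax <- distortion_factors(n, alpha)$axial
  tilt_span <- abs(tan(alpha * pi / 180)) * px / pz * n_x
  as.integer(ceiling(scene$top_plate_row + H / (pz * d_ax) + tilt_span) + 15L)
}

# ROI height rule shared with the tracker: 12 native axial px for large
# (> 200 um) separations, 18 px for small ones.
roi_height_px <- function(H_um) if (H_um > 200) 12L else 18L

# Stratified initial particle positions: a fixed number per (depth band x
# lateral band) cell so that every ROI row holds trackable particles in all
# frames. Depth bands follow the ROI height rule; lateral bands are ~150 um.
seed_particles <- function(scene, acq, geom) {
  H <- geom$separation_H
  pz <- acq$pixel_size_z_free_space
  d_ax <- distortion_factors(geom$refractive_index_n, geom$tilt_alpha)$axial
  band_h <- roi_height_px(H) * pz * d_ax          # physical band height, um
  margin <- band_h / 2
  n_bands_z <- max(2L, floor((H - 2 * margin) / band_h))
  fov_x <- acq$a_lines_per_frame * acq$pixel_size_x_free_space
  band_w <- 100 * acq$pixel_size_x_free_space
  n_bands_x <- max(1L, floor(fov_x / band_w))
  n_per <- max(1L, round(scene$particles_per_roi))
  grid <- expand.grid(iz = seq_len(n_bands_z), ix = seq_len(n_bands_x),
                      p = seq_len(n_per))
  # keep particles in the central 70% of each lateral band so small plate
  # excursions never empty an ROI
  x0 <- (grid$ix - 1) * band_w + band_w * (0.15 + 0.7 * stats::runif(nrow(grid)))
  z0 <- margin + (grid$iz - 1 + stats::runif(nrow(grid))) * band_h
  z0 <- pmin(z0, H - margin)
  tibble::tibble(particle = seq_len(nrow(grid)), x = x0, z = z0)
}

#' Advect particles with the Couette flow
#'
#' Moves particles laterally by the time integral of [couette_velocity()] at
#' their depth between `t0` and `t1`; depths are unchanged (no Brownian
#' motion, no migration). Because the flow is linear in depth, the integral
#' is `(z / H) * (plate_position(t1) - plate_position(t0))`, exact for both
#' waveforms. If `wrap_domain` is given, lateral positions wrap around it so
#' particle density stays constant.
#'
#' @param positions Tibble with columns `x`, `z` (micrometers).
#' @param waveform A [driving_waveform()].
#' @param geom A [chamber_geometry()].
#' @param t0,t1 Start and end times in seconds (`t1 >= t0`).
#' @param wrap_domain Optional `c(min, max)` lateral wrap interval.
#' @return The positions tibble with updated `x`.
#' @export
advect_particles <- function(positions, waveform, geom, t0, t1,
                             wrap_domain = NULL) {
  stopifnot(t1 >= t0)
  dxp <- plate_position(t1, waveform) - plate_position(t0, waveform)
  x <- positions$x + (positions$z / geom$separation_H) * dxp
  if (!is.null(wrap_domain)) {
    w <- wrap_domain[2] - wrap_domain[1]
    x <- wrap_domain[1] + ((x - wrap_domain[1]) %% w)
  }
  positions$x <- x
  positions
}

# Apparent (image) row of the top plate at native column c (1-based), px.
# The chamber tilt makes the plate line slope across the image.
top_plate_row_at <- function(cols, scene, acq, geom) {
  slope_px <- tan(geom$tilt_alpha * pi / 180) *
    acq$pixel_size_x_free_space / acq$pixel_size_z_free_space
  scene$top_plate_row + slope_px * (cols - 1)
}

#' Render one synthetic B-mode frame
#'
#' Draws the two plate interfaces as bright tilted ridges and each particle as
#' an anisotropic Gaussian blob at its refraction-scaled pixel position, with
#' depth sensitivity roll-off and additive clipped Gaussian noise. A particle
#' at physical depth `d` below the top plate appears `d / (pz * D_axial)`
#' pixels below the local plate row, the inverse of the preprocessing depth
#' calibration; lateral positions are foreshortened by `cos(alpha)`. When
#' `scene$intra_frame_timing` is set, column `c` is rendered at time
#' `frame_time + (c - 1) / a_line_rate` so intra-frame motion is modelled.
#'
#' @param positions Particle positions at `frame_time` (tibble `x`, `z`), as
#'   produced by [advect_particles()]. Positions outside the field of view
#'   are silently not rendered.
#' @param scene A [scene_config()].
#' @param acq An [acquisition_params()].
#' @param geom A [chamber_geometry()].
#' @param waveform A [driving_waveform()] (used for intra-frame motion).
#' @param frame_time Frame start time in seconds.
#' @param noise If `FALSE`, skip the noise draw (used for deterministic
#'   expectations).
#' @return Numeric matrix `[n_z, n_x]` with intensities in `[0, 1]`.
#' @export
render_frame <- function(positions, scene, acq, geom, waveform, frame_time,
                         noise = TRUE) {
  n_z <- acq$n_z
  n_x <- acq$a_lines_per_frame
  px <- acq$pixel_size_x_free_space
  pz <- acq$pixel_size_z_free_space
  alpha <- geom$tilt_alpha
  cosa <- cos(alpha * pi / 180)
  d_ax <- distortion_factors(geom$refractive_index_n, alpha)$axial
  img <- matrix(0, n_z, n_x)
  rows <- seq_len(n_z)
  cols <- seq_len(n_x)

  # plate ridges (gaussian in z, sigma from the axial PSF)
  sig_z <- scene$psf_axial_fwhm / (2 * sqrt(2 * log(2))) / pz
  r_top <- top_plate_row_at(cols, scene, acq, geom)
  r_bot <- r_top + geom$separation_H / (pz * d_ax)
  roll <- function(r) exp(-(r * pz) / scene$rolloff_decay_length)
  for (c in cols) {
    img[, c] <- scene$plate_intensity *
      (exp(-(rows - r_top[c])^2 / (2 * sig_z^2)) * roll(r_top[c]) +
       exp(-(rows - r_bot[c])^2 / (2 * sig_z^2)) * roll(r_bot[c]))
  }

  if (isTRUE(scene$artifact_streak)) {
    # static bright streak just below the top plate (autocorrelation artifact)
    r_art <- round(mean(r_top)) + 6L
    if (r_art >= 1 && r_art <= n_z) {
      img[r_art, ] <- pmax(img[r_art, ], 0.9 * scene$plate_intensity)
    }
  }

  # particle blobs: sigma = PSF (+ particle size in quadrature)
  fw_x <- sqrt(scene$psf_lateral_fwhm^2 + scene$particle_diameter^2)
  fw_z <- sqrt(scene$psf_axial_fwhm^2 + scene$particle_diameter^2)
  sig_x <- fw_x / (2 * sqrt(2 * log(2))) / px
  sig_zp <- fw_z / (2 * sqrt(2 * log(2))) / pz
  half_x <- ceiling(4 * sig_x)
  half_z <- ceiling(4 * sig_zp)

  if (nrow(positions) > 0) {
    for (p in seq_len(nrow(positions))) {
      zp <- positions$z[p]
      u0 <- positions$x[p] * cosa / px + 1    # image column at frame start
      cand <- seq(max(1L, floor(u0 - half_x - 2)),
                  min(n_x, ceiling(u0 + half_x + 2)))
      if (length(cand) == 0) next
      if (isTRUE(scene$intra_frame_timing)) {
        tc <- frame_time + (cand - 1) / acq$a_line_rate
        xp <- positions$x[p] + (zp / geom$separation_H) *
          (plate_position(tc, waveform) - plate_position(frame_time, waveform))
        u <- xp * cosa / px + 1
      } else {
        u <- rep(u0, length(cand))
      }
      g <- exp(-(cand - u)^2 / (2 * sig_x^2))
      keep <- g > 1e-5
      if (!any(keep)) next
      cand <- cand[keep]; g <- g[keep]
      r_p <- r_top[cand] + zp / (pz * d_ax)
      amp <- scene$particle_intensity * exp(-(r_p * pz) /
                                              scene$rolloff_decay_length)
      for (ii in seq_along(cand)) {
        rws <- seq(max(1L, floor(r_p[ii] - half_z)),
                   min(n_z, ceiling(r_p[ii] + half_z)))
        if (length(rws) == 0) next
        img[rws, cand[ii]] <- img[rws, cand[ii]] +
          amp[ii] * g[ii] * exp(-(rws - r_p[ii])^2 / (2 * sig_zp^2))
      }
    }
  }

  if (noise && scene$noise_std > 0) {
    img <- img + matrix(stats::rnorm(n_z * n_x, 0, scene$noise_std), n_z, n_x)
  }
  img <- pmin(pmax(img, 0), 1)
  # quantize to 16-bit levels so TIFF round trips are exact
  round(img * 65535) / 65535
}

#' Generate a synthetic B-mode stack with ground truth
#'
#' Renders `acq$n_frames` frames at the acquisition frame interval, advecting
#' a stratified set of tracer particles with the closed-form Couette flow
#' (including the mechanical start delay of the waveform). The result is
#' deterministic given `scene$seed`.
#'
#' @param scene A [scene_config()].
#' @param acq An [acquisition_params()].
#' @param waveform A [driving_waveform()].
#' @param geom A [chamber_geometry()].
#' @return An [oct_stack()] whose `meta` carries `waveform`, `geom`, `scene`
#'   parameters and a `ground_truth` list with the true shear rate
#'   (amplitude), waveform parameters, `H`, tilt, refractive index and
#'   per-frame particle positions.
#' @examples
#' \donttest{
#' st <- generate_stack(scene_config(seed = 7),
#'                      acquisition_params(10000, 250, 0.002, 6, 2,
#'                                         n_frames = 10, n_z = 247),
#'                      driving_waveform("triangle", 0.5, plate_speed = 60),
#'                      chamber_geometry(292, 1, 1.45))
#' }
#' @export
generate_stack <- function(scene, acq, waveform, geom) {
  if (geom$separation_H / (acq$pixel_size_z_free_space) >= acq$n_z) {
    rlang::abort("Image height cannot contain the plate separation.",
                 class = "octflow_error_validation")
  }
  withr::with_seed(scene$seed, {
    pos0 <- seed_particles(scene, acq, geom)
    fov_x <- acq$a_lines_per_frame * acq$pixel_size_x_free_space
    excur <- waveform$peak_to_peak / 2 + 1
    wrap <- c(-excur - 5, fov_x + excur + 5)
    times <- (seq_len(acq$n_frames) - 1) * acq$frame_interval
    frames <- array(0, c(acq$n_z, acq$a_lines_per_frame, acq$n_frames))
    truth_pos <- vector("list", acq$n_frames)
    for (k in seq_len(acq$n_frames)) {
      pos_k <- advect_particles(pos0, waveform, geom, 0, times[k],
                                wrap_domain = wrap)
      frames[, , k] <- render_frame(pos_k, scene, acq, geom, waveform,
                                    times[k])
      truth_pos[[k]] <- tibble::tibble(frame = k, particle = pos_k$particle,
                                       x = pos_k$x, z = pos_k$z)
    }
    true_rate <- if (waveform$kind == "triangle") {
      shear_rate_constant(waveform$plate_speed, geom$separation_H)
    } else {
      shear_rate_amplitude(waveform$peak_speed, geom$separation_H)
    }
    meta <- list(
      waveform = waveform,
      geom = geom,
      scene = unclass(scene),
      ground_truth = list(
        shear_rate = true_rate,
        frequency = waveform$frequency,
        phase = waveform$phase,
        H = geom$separation_H,
        tilt_alpha = geom$tilt_alpha,
        refractive_index = geom$refractive_index_n,
        positions = dplyr::bind_rows(truth_pos)))
    oct_stack(frames,
              a_line_rate = acq$a_line_rate,
              dead_time = acq$dead_time,
              pixel_size_x = acq$pixel_size_x_free_space,
              pixel_size_z = acq$pixel_size_z_free_space,
              time = times, meta = meta)
  })
}

#' Simulation presets mirroring the validation experiments
#'
#' `preset_constant()` reproduces the constant-shear configuration: a 0.5 Hz
#' triangle drive, ~300 um plate separation, 250 A-lines at 10 kHz with 2 ms
#' dead time (37 Hz frame rate), 1.5 mm lateral field of view.
#' `preset_sinusoid()` reproduces the oscillatory-shear configuration: 24 um
#' peak-to-peak sinusoidal drive at 1-10 Hz, ~150 um separation, 208 A-lines
#' at 69 kHz (199 Hz frame rate), 1.2 mm field of view. Frame counts cover at
#' least two driving cycles (up to six, as acquired in practice) within a
#' 200-frame cap that keeps stacks tractable.
#'
#' @param plate_speed Triangle plate speed `Vx0` in um/s.
#' @param frequency Sinusoid driving frequency in Hz.
#' @param H Plate separation in micrometers.
#' @param tilt_alpha Chamber tilt in degrees.
#' @param n Sample refractive index.
#' @param peak_to_peak Sinusoid peak-to-peak displacement in um.
#' @param scene A [scene_config()] (override to change noise, seed, ...).
#' @param n_cycles Driving cycles to cover (default 2 for the triangle, up to
#'   6 for the sinusoid).
#' @return A list with elements `scene`, `acq`, `waveform`, `geom`.
#' @export
preset_constant <- function(plate_speed = 60, H = 292, tilt_alpha = 1,
                            n = 1.45, scene = scene_config(), n_cycles = 2) {
  wf <- driving_waveform("triangle", frequency = 0.5,
                         plate_speed = plate_speed)
  acq0 <- 250 / 10000 + 0.002
  n_frames <- min(200L, ceiling((n_cycles / wf$frequency + 0.05) / acq0))
  geom <- chamber_geometry(H, tilt_alpha, n)
  n_z <- preset_image_height(scene, H, n, tilt_alpha, 1500 / 250, 2, 250)
  acq <- acquisition_params(10000, 250, 0.002,
                            pixel_size_x_free_space = 1500 / 250,
                            pixel_size_z_free_space = 2,
                            n_frames = n_frames, n_z = n_z)
  list(scene = scene, acq = acq, waveform = wf, geom = geom)
}

#' @rdname preset_constant
#' @export
preset_sinusoid <- function(frequency = 10, H = 150, peak_to_peak = 24,
                            tilt_alpha = 1, n = 1.45,
                            scene = scene_config(), n_cycles = 6) {
  wf <- driving_waveform("sinusoid", frequency = frequency,
                         peak_to_peak = peak_to_peak)
  acq0 <- 208 / 69000 + 0.002
  n_frames <- min(200L, ceiling((n_cycles / frequency + 0.05) / acq0))
  geom <- chamber_geometry(H, tilt_alpha, n)
  n_z <- preset_image_height(scene, H, n, tilt_alpha, 1200 / 208, 2, 208)
  acq <- acquisition_params(69000, 208, 0.002,
                            pixel_size_x_free_space = 1200 / 208,
                            pixel_size_z_free_space = 2,
                            n_frames = n_frames, n_z = n_z)
  list(scene = scene, acq = acq, waveform = wf, geom = geom)
}
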