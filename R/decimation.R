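#' Mask frames near triangle-waveform turnarounds
#'
#' For a triangle drive, frames acquired within `n_pad` frame intervals of a
#' waveform peak or valley are omitted ("padded") so that stage reversal
#' transients do not enter the velocity averages. For a sinusoid, all frames
#' are analyzed and the mask is all-`TRUE`.
#'
#' @param time Frame start times in seconds.
#' @param waveform A [driving_waveform()].
#' @param frame_dt Frame interval in seconds.
#' @param n_pad Frames of padding on each side of a turnaround (default 2).
#' @return Logical vector: `TRUE` for frames kept.
#' @export
pad_turnarounds <- function(time, waveform, frame_dt, n_pad = 2) {
  if (waveform$kind != "triangle") return(rep(TRUE, length(time)))
  Tp <- 1 / waveform$frequency
  turns <- turnaround_times(waveform, max(time) + Tp)
  keep <- rep(TRUE, length(time))
  tol <- n_pad * frame_dt + 1e-9
  for (tt in turns) keep[abs(time - tt) <= tol] <- FALSE
  keep
}

# Turnaround instants of a triangle drive up to t_max: delay + T/4 + m T/2.
turnaround_times <- function(waveform, t_max) {
  Tp <- 1 / waveform$frequency
  t0 <- waveform$mechanical_delay + Tp / 4
  seq(t0, t_max, by = Tp / 2)
}

# Sweep (half-cycle) index of each frame of a triangle drive; frames before
# motion starts get sweep 0.
sweep_index <- function(time, waveform) {
  Tp <- 1 / waveform$frequency
  tau <- time - waveform$mechanical_delay
  s <- floor((tau + Tp / 4) / (Tp / 2)) + 1L
  s[tau < 0] <- 0L
  as.integer(s)
}

# Mean absolute bottom-row displacement (upsampled px) measured over valid
# bottom-row ROIs with a fixed decimation, restricted to `frames` (indices
# into the stack) whose pair partner is also in `frames`. Returns NA when no
# measurable pair exists.
mean_bottom_displacement <- function(flat, grid, thresholds, validity, dk,
                                     frames, search_x, search_z = 2) {
  i <- grid$n_row
  js <- which(validity[i, ])
  vals <- c()
  for (k in frames) {
    if (!((k + dk) %in% frames)) next
    for (j in js) {
      r1 <- apply_threshold(roi_pixels(flat, grid, i, j, k), thresholds[i])
      r2 <- apply_threshold(roi_pixels(flat, grid, i, j, k + dk),
                            thresholds[i])
      m <- tryCatch(ncc_displacement(r1, r2, search_x, search_z),
                    octflow_error_zero_variance = function(e) NULL)
      if (!is.null(m)) vals <- c(vals, abs(m$xshift))
    }
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Constant-mode frame decimation plan
#'
#' Chooses one frame decimation `dk_i` per ROI row so that the expected
#' inter-pair displacement is about `p_target` upsampled pixels (one native
#' pixel by default), exaggerating motion where it is slow. The bottom-row
#' per-frame displacement `d_N` is first measured by normalized
#' cross-correlation within the first complete half cycle; because sub-pixel
#' per-frame motion cannot be measured directly at unit decimation, the
#' estimate starts at `dk = 1` and doubles the decimation until the mean
#' measured displacement reaches 2 pixels (or the half-sweep cap), then
#' divides back. Row estimates follow the linear profile,
#' `d_i = d_N * z_i / z_N` (zero velocity extrapolated at the top plate),
#' and `dk_i = clamp(ceil(p_target / d_i), 1, F - 1)` with `F` the frames
#' per half sweep.
#'
#' @param flat A `flattened_stack`.
#' @param grid An [partition_grid()] result.
#' @param thresholds Per-row thresholds.
#' @param validity Validity mask from [build_validity()].
#' @param waveform The triangle [driving_waveform()].
#' @param p_target Target displacement in upsampled pixels (default: the
#'   upsampling factor, i.e. one native pixel).
#' @param keep Frame mask from [pad_turnarounds()].
#' @return A list of class `decimation_plan`: `mode = "constant"`, integer
#'   `dk` per row, a logical `measurable` per row (rows whose pairs cannot
#'   accumulate at least 2 px are quantization-dominated and excluded from
#'   tracking; the three deepest rows are always kept), the bottom-row
#'   estimate `d_bottom` (px/frame) and `frames_per_sweep`.
#' @export
plan_decimation_constant <- function(flat, grid, thresholds, validity,
                                     waveform, p_target = grid$upsample,
                                     keep = NULL) {
  dt <- frame_interval(flat)
  if (is.null(keep)) keep <- pad_turnarounds(flat$time, waveform, dt)
  Fhalf <- max(2L, floor(1 / (2 * waveform$frequency) / dt))
  sweeps <- sweep_index(flat$time, waveform)
  # first sweep with enough kept frames
  tab <- table(sweeps[keep & sweeps > 0])
  full <- as.integer(names(tab)[tab >= max(2, Fhalf %/% 2)])
  if (length(full) == 0) {
    rlang::abort("No complete half cycle available after padding.",
                 class = "octflow_error_invalid_stack")
  }
  frames <- which(keep & sweeps == full[1])
  v_max <- waveform$plate_speed
  px_per_um <- 1 / flat$pixel_size_x
  dk_est <- 1L
  d_meas <- NA_real_
  repeat {
    search_x <- ceiling(dk_est * dt * v_max * px_per_um) + 2L
    d_meas <- mean_bottom_displacement(flat, grid, thresholds, validity,
                                       dk_est, frames, search_x)
    if (!is.na(d_meas) && (d_meas >= 2 || dk_est * 2 >= Fhalf)) break
    if (dk_est * 2 >= Fhalf) break
    dk_est <- dk_est * 2L
  }
  if (is.na(d_meas) || d_meas < 1) {
    rlang::abort("Insufficient motion in the bottom ROI row.",
                 class = "octflow_error_insufficient_motion")
  }
  d_bottom <- d_meas / dk_est
  # largest lag realizable inside a padded half sweep
  kept_sweeps <- split(which(keep & sweeps > 0), sweeps[keep & sweeps > 0])
  max_lag <- max(vapply(kept_sweeps, function(k) diff(range(k)), numeric(1)))
  z <- grid$depth_um
  d_i <- d_bottom * z / z[grid$n_row]
  dk <- pmin(pmax(ceiling(p_target / d_i), 1), min(Fhalf - 1, max_lag))
  # rows whose pairs cannot accumulate ~2 px are quantization-dominated and
  # are not tracked; the three deepest rows are always kept
  measurable <- d_i * dk >= 2
  measurable[max(1, grid$n_row - 2):grid$n_row] <- TRUE
  structure(list(mode = "constant", dk = as.integer(dk),
                 measurable = measurable,
                 d_bottom = d_bottom, frames_per_sweep = Fhalf),
            class = "decimation_plan")
}

#' Sinusoidal-mode frame decimation plan
#'
#' Extends the constant-mode plan to a decimation varying in time,
#' `dk(k)_i`, tracking the instantaneous driving speed. The bottom-row
#' velocity amplitude is estimated by normalized cross-correlation at a
#' coarse decimation (the quarter-period cap, where displacements are well
#' above a pixel); the expected instantaneous speed of row `i` at frame `k`
#' is then `v_i(k) = V_N * (z_i / z_N) * |cos(w t_k + phi)|`, floored at
#' `0.05 * V_N`, and `dk(k)_i = clamp(ceil(p_target / v_i(k)), 1, cap)` with
#' `cap = floor(T / (4 dt))`: no pair spans more than one-quarter of a
#' driving period, which keeps the finite-difference attenuation factor
#' `sinc(w dk dt / 2)` above 0.9 so that [velocities_sinusoidal()] can
#' compensate it exactly while slow rows still accumulate displacements of
#' several pixels.
#'
#' @inheritParams plan_decimation_constant
#' @param waveform The sinusoidal [driving_waveform()].
#' @return A list of class `decimation_plan`: `mode = "sinusoidal"`, integer
#'   matrix `dk` (`n_row` by `n_frames`), a logical `measurable` per row
#'   (as in [plan_decimation_constant()]), the amplitude estimate
#'   `v_bottom` (px/frame) and `cap`.
#' @export
plan_decimation_sinusoidal <- function(flat, grid, thresholds, validity,
                                       waveform,
                                       p_target = grid$upsample) {
  dt <- frame_interval(flat)
  Tp <- 1 / waveform$frequency
  cap <- floor(Tp / (4 * dt))
  if (cap < 1 || Tp / dt < 4) {
    rlang::abort("Frame rate insufficient for this driving frequency.",
                 class = "octflow_error_frame_rate")
  }
  frames <- seq_len(n_frames(flat))
  v_max <- waveform$peak_speed
  px_per_um <- 1 / flat$pixel_size_x
  search_x <- ceiling(cap * dt * v_max * px_per_um) + 2L
  # amplitude estimate from upper-decile displacements at the cap decimation
  i <- grid$n_row
  js <- which(validity[i, ])
  vals <- c()
  for (k in frames) {
    if (!((k + cap) %in% frames)) next
    for (j in js) {
      r1 <- apply_threshold(roi_pixels(flat, grid, i, j, k), thresholds[i])
      r2 <- apply_threshold(roi_pixels(flat, grid, i, j, k + cap),
                            thresholds[i])
      m <- tryCatch(ncc_displacement(r1, r2, search_x, 2),
                    octflow_error_zero_variance = function(e) NULL)
      if (!is.null(m)) vals <- c(vals, abs(m$xshift) / cap)
    }
  }
  if (length(vals) == 0 || stats::quantile(vals, 0.9) <= 0) {
    rlang::abort("Insufficient motion in the bottom ROI row.",
                 class = "octflow_error_insufficient_motion")
  }
  v_bottom <- unname(stats::quantile(vals, 0.9))
  w <- 2 * pi * waveform$frequency
  t_mid <- flat$time + dim(flat$frames)[2] / flat$upsample / 2 /
    flat$a_line_rate
  phase_t <- w * (t_mid - waveform$mechanical_delay) + waveform$phase
  z <- grid$depth_um
  dk <- matrix(1L, grid$n_row, length(frames))
  for (i2 in seq_len(grid$n_row)) {
    v_ik <- v_bottom * (z[i2] / z[grid$n_row]) * abs(cos(phase_t))
    v_ik <- pmax(v_ik, 0.05 * v_bottom)
    dk[i2, ] <- as.integer(pmin(pmax(ceiling(p_target / v_ik), 1), cap))
  }
  measurable <- v_bottom * (z / z[grid$n_row]) * cap >= 2
  measurable[max(1, grid$n_row - 2):grid$n_row] <- TRUE
  structure(list(mode = "sinusoidal", dk = dk, v_bottom = v_bottom,
                 measurable = measurable,
                 cap = as.integer(cap)),
            class = "decimation_plan")
}
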