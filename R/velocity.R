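#' Convert a displacement rate to physical velocity
#'
#' Velocities measured in (upsampled) pixels per frame are converted to
#' micrometers per second with the current lateral pixel size (free-space
#' size over the upsampling factor), the transverse tilt distortion factor
#' and the frame interval. Axial distortion does not enter: motion is
#' lateral, and refraction only calibrates depth.
#'
#' @param value Velocity in current pixels per frame.
#' @param pixel_size_x Current lateral pixel size in micrometers.
#' @param transverse Transverse distortion factor (`1 / cos(alpha)`).
#' @param frame_dt Frame interval in seconds.
#' @return Velocity in um/s.
#' @examples
#' convert_units(1, 6 / 4, 1, 0.00503)
#' @export
convert_units <- function(value, pixel_size_x, transverse, frame_dt) {
  if (is.null(pixel_size_x) || is.null(transverse) || is.null(frame_dt) ||
      any(is.na(c(pixel_size_x, transverse, frame_dt)))) {
    rlang::abort("Missing conversion metadata.",
                 class = "octflow_error_config")
  }
  value * pixel_size_x * transverse / frame_dt
}

# Lateral NCC search extent for a given decimation: theoretical maximum
# bottom-plate displacement over the pair interval, plus a 2 px margin.
search_extent <- function(dk, frame_dt, v_max, pixel_size_x, margin = 2L) {
  ceiling(dk * frame_dt * v_max / pixel_size_x) + margin
}

#' Measure per-ROI displacements
#'
#' Runs [ncc_displacement()] on thresholded ROI pairs according to a
#' [plan_decimation_constant()] or [plan_decimation_sinusoidal()] plan.
#' Constant mode pairs frames within each unpadded half sweep; sinusoidal
#' mode pairs every frame `k` with `k + dk(k)_i`. Velocity sample times are
#' placed mid-interval (continuous time), at the ROI row's central A-line.
#'
#' @param flat A `flattened_stack`.
#' @param grid An [partition_grid()] result.
#' @param thresholds Per-row thresholds from [threshold_rows()].
#' @param validity Validity mask from [build_validity()].
#' @param plan A `decimation_plan`.
#' @param waveform The [driving_waveform()].
#' @param keep Frame mask from [pad_turnarounds()] (constant mode).
#' @param search_z Axial search extent in pixels (default 2; axial motion is
#'   expected to be negligible).
#' @return A tibble with columns `k`, `i`, `j`, `dk`, `xshift`, `zshift`,
#'   `rho`, `sweep` (constant mode; `NA` otherwise) and `t_mid` (s).
#' @export
measure_displacements <- function(flat, grid, thresholds, validity, plan,
                                  waveform, keep = NULL, search_z = 2L) {
  dt <- frame_interval(flat)
  Q <- n_frames(flat)
  v_max <- if (waveform$kind == "triangle") waveform$plate_speed
           else waveform$peak_speed
  # time of the central A-line of the native frame
  t_frame <- flat$time + dim(flat$frames)[2] / flat$upsample / 2 /
    flat$a_line_rate
  rows <- list()
  n_out <- 0L
  add <- function(rec) {
    n_out <<- n_out + 1L
    rows[[n_out]] <<- rec
  }
  if (plan$mode == "constant") {
    if (is.null(keep)) keep <- pad_turnarounds(flat$time, waveform, dt)
    sweeps <- sweep_index(flat$time, waveform)
    for (i in seq_len(grid$n_row)) {
      if (!is.null(plan$measurable) && !plan$measurable[i]) next
      dk <- plan$dk[i]
      sx <- search_extent(dk, dt, v_max, flat$pixel_size_x)
      for (k in seq_len(Q - dk)) {
        if (!keep[k] || !keep[k + dk]) next
        if (sweeps[k] < 1 || sweeps[k] != sweeps[k + dk]) next
        for (j in which(validity[i, ])) {
          r1 <- apply_threshold(roi_pixels(flat, grid, i, j, k),
                                thresholds[i])
          r2 <- apply_threshold(roi_pixels(flat, grid, i, j, k + dk),
                                thresholds[i])
          m <- tryCatch(ncc_displacement(r1, r2, sx, search_z),
                        octflow_error_zero_variance = function(e) NULL)
          if (is.null(m)) next
          add(list(k = k, i = i, j = j, dk = dk, xshift = m$xshift,
                   zshift = m$zshift, rho = m$rho, sweep = sweeps[k],
                   t_mid = t_frame[k] + dk * dt / 2))
        }
      }
    }
  } else {
    for (i in seq_len(grid$n_row)) {
      if (!is.null(plan$measurable) && !plan$measurable[i]) next
      dks <- plan$dk[i, ]
      sx_by_dk <- vapply(sort(unique(dks)), function(d)
        search_extent(d, dt, v_max, flat$pixel_size_x), numeric(1))
      names(sx_by_dk) <- sort(unique(dks))
      for (k in seq_len(Q)) {
        dk <- dks[k]
        if (k + dk > Q) next
        sx <- sx_by_dk[[as.character(dk)]]
        for (j in which(validity[i, ])) {
          r1 <- apply_threshold(roi_pixels(flat, grid, i, j, k),
                                thresholds[i])
          r2 <- apply_threshold(roi_pixels(flat, grid, i, j, k + dk),
                                thresholds[i])
          m <- tryCatch(ncc_displacement(r1, r2, sx, search_z),
                        octflow_error_zero_variance = function(e) NULL)
          if (is.null(m)) next
          add(list(k = k, i = i, j = j, dk = dk, xshift = m$xshift,
                   zshift = m$zshift, rho = m$rho, sweep = NA_integer_,
                   t_mid = t_frame[k] + dk * dt / 2))
        }
      }
    }
  }
  if (n_out == 0L) {
    rlang::abort("No displacement could be measured.",
                 class = "octflow_error_invalid_stack")
  }
  dplyr::bind_rows(rows)
}

#' Depth-resolved speed profile from a constant-shear displacement field
#'
#' Per-ROI velocities `xshift / dk` (pixels per frame) are averaged over the
#' frames of each half cycle `q`, giving `V(q)_{i,j}`; the speed of each ROI
#' row is then the mean of `|V(q)_{i,j}|` pooled over columns and half
#' cycles (absolute values fold the forward and backward sweeps together),
#' with its standard deviation. Speeds are converted to um/s.
#'
#' @param field Displacement tibble from [measure_displacements()].
#' @param grid An [partition_grid()] result.
#' @param pixel_size_x Current lateral pixel size (um).
#' @param transverse Transverse distortion factor.
#' @param frame_dt Frame interval (s).
#' @return A tibble with one row per ROI row: `i`, `depth_um`,
#'   `speed_um_s`, `sd_um_s`, `quant_um_s` (the integer-localization error
#'   floor, see Details), `n_meas` (half-cycle x column averages used).
#' @export
velocities_constant <- function(field, grid, pixel_size_x, transverse,
                                frame_dt) {
  per_q <- field |>
    dplyr::mutate(v = .data$xshift / .data$dk) |>
    dplyr::group_by(.data$i, .data$j, .data$sweep) |>
    dplyr::summarise(v_q = mean(.data$v), .groups = "drop")
  prof <- per_q |>
    dplyr::group_by(.data$i) |>
    dplyr::summarise(
      speed_px = mean(abs(.data$v_q)),
      sd_px = stats::sd(abs(.data$v_q)),
      n_meas = dplyr::n(), .groups = "drop")
  prof$sd_px[is.na(prof$sd_px)] <- 0
  # irreducible integer-localization error of a displacement: +/- 0.5 px
  # uniform, sd 0.5 / sqrt(3) ~ 0.289 px, divided by the row decimation; it
  # does not average out across identical pairs, so it floors the row error
  dk_by_i <- field |>
    dplyr::distinct(.data$i, .data$dk)
  prof <- dplyr::left_join(prof, dk_by_i, by = "i")
  quant_px <- 0.5 / sqrt(3) / prof$dk
  tibble::tibble(
    i = prof$i,
    depth_um = grid$depth_um[prof$i],
    speed_um_s = convert_units(prof$speed_px, pixel_size_x, transverse,
                               frame_dt),
    sd_um_s = convert_units(prof$sd_px, pixel_size_x, transverse, frame_dt),
    quant_um_s = convert_units(quant_px, pixel_size_x, transverse, frame_dt),
    n_meas = prof$n_meas)
}

#' Depth-resolved velocity waveforms from a sinusoidal displacement field
#'
#' Per-ROI velocities `xshift / dk(k)_i`, assigned to the middle of their
#' pair interval, are averaged (unweighted) over the valid ROI columns of
#' each row at each sample time; the across-column standard deviation is
#' retained for fit weighting. Velocities are converted to um/s.
#'
#' Because a displacement over `dk` frames measures the average velocity of
#' the interval, the sample at the interval midpoint is attenuated by
#' exactly `sinc(w dk dt / 2)` for a sinusoid of angular frequency `w`;
#' when `omega` is supplied each sample is divided by this factor, removing
#' the depth-dependent attenuation that the larger decimations of the slow
#' rows would otherwise imprint on the amplitude profile.
#'
#' @inheritParams velocities_constant
#' @param omega Driving angular frequency (rad/s) for the finite-difference
#'   correction; `NULL` skips it.
#' @return A tibble with one row per (ROI row, sample time): `i`,
#'   `depth_um`, `t` (s), `v_um_s`, `sd_um_s` (`NA` when only one column),
#'   `n_cols`.
#' @export
velocities_sinusoidal <- function(field, grid, pixel_size_x, transverse,
                                  frame_dt, omega = NULL) {
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  corr <- if (is.null(omega)) rep(1, nrow(field))
          else sinc(omega * field$dk * frame_dt / 2)
  wav <- field |>
    dplyr::mutate(v = .data$xshift / .data$dk / corr) |>
    dplyr::group_by(.data$i, .data$k, .data$t_mid) |>
    dplyr::summarise(v_px = mean(.data$v),
                     sd_px = stats::sd(.data$v),
                     dk_pair = .data$dk[1],
                     n_cols = dplyr::n(), .groups = "drop")
  tibble::tibble(
    i = wav$i,
    depth_um = grid$depth_um[wav$i],
    t = wav$t_mid,
    v_um_s = convert_units(wav$v_px, pixel_size_x, transverse, frame_dt),
    quant_um_s = convert_units(0.5 / sqrt(3) / wav$dk_pair, pixel_size_x,
                               transverse, frame_dt),
    sd_um_s = ifelse(is.na(wav$sd_px), NA_real_,
                     convert_units(wav$sd_px, pixel_size_x, transverse,
                                   frame_dt)),
    n_cols = wav$n_cols)
}
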