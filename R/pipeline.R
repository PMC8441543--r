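#' Tracking configuration
#'
#' All tunable parameters of the tracking pipeline in one list, with
#' defaults matching the validated operating procedure: discard the first
#' 30 ms, upsample laterally 4x, per-row threshold at mean + 1.5 SD, plates
#' parallel within 1 degree, 2 frames of turnaround padding, a decimation
#' target displacement of one native pixel, 2 px axial search.
#'
#' @param discard_time Start-up discard window in seconds.
#' @param upsample Lateral upsampling factor.
#' @param upsample_method `"cubic"` or `"linear"` interpolation.
#' @param threshold_k SD multiplier of the per-row intensity threshold.
#' @param parallel_tol Plate parallelism tolerance in degrees.
#' @param pad_frames Frames of turnaround padding on each side.
#' @param p_target Decimation target displacement in upsampled pixels
#'   (`NULL`: two native pixels, i.e. twice the upsampling factor; integer
#'   peak localization then bounds the per-measurement speed error at about
#'   6%, which the row and cycle averaging reduces further).
#' @param search_z Axial NCC search extent in pixels.
#' @param refractive_index Sample refractive index override (`NULL`: taken
#'   from stack metadata, falling back to 1.45).
#' @param through_origin Force the shear-rate regression through zero
#'   velocity at the top plate.
#' @return A list of class `track_config`.
#' @export
track_config <- function(discard_time = 0.03,
                         upsample = 4L,
                         upsample_method = "cubic",
                         threshold_k = 1.5,
                         parallel_tol = 1,
                         pad_frames = 2,
                         p_target = NULL,
                         search_z = 2L,
                         refractive_index = NULL,
                         through_origin = FALSE) {
  structure(
    list(discard_time = discard_time, upsample = as.integer(upsample),
         upsample_method = upsample_method, threshold_k = threshold_k,
         parallel_tol = parallel_tol, pad_frames = pad_frames,
         p_target = p_target, search_z = as.integer(search_z),
         refractive_index = refractive_index,
         through_origin = through_origin),
    class = "track_config")
}

#' Run the full tracking pipeline on a stack
#'
#' Orchestrates the analysis chain on a raw B-mode stack: start-up discard,
#' lateral upsampling, plate detection and tilt flattening, ROI grid
#' partition, per-row thresholding and validity checks, frame decimation
#' planning, normalized cross-correlation displacement measurement, velocity
#' profile (triangle drive) or per-depth velocity waveforms with sinusoid
#' fits (sinusoidal drive), and the weighted shear-rate regression. The
#' waveform is taken from `stack$meta$waveform` unless given.
#'
#' @param stack An [oct_stack()].
#' @param waveform A [driving_waveform()]; defaults to the stack metadata.
#' @param config A [track_config()].
#' @return An object of class `oct_ptv_result`: a list with `mode`,
#'   `profile` (per-row tibble), `shear` (a `shear_fit`), `frequency` /
#'   `frequency_se` / `phase_deg` / `phase_se_deg` (sinusoidal mode, pooled
#'   across rows by inverse-variance weighting), `row_fits` (tibble of
#'   per-row sinusoid fits), `waveforms` (sinusoidal velocity samples),
#'   `displacements` (the audit table of every NCC measurement),
#'   `measured_H`, `measured_alpha`, `thresholds`, `validity`, `plan`,
#'   `grid`, `config` and `theory` (theoretical shear rate from the set
#'   plate speed and the measured separation).
#' @export
track_stack <- function(stack, waveform = NULL, config = track_config()) {
  if (is.null(waveform)) waveform <- stack$meta$waveform
  if (is.null(waveform)) {
    rlang::abort("No driving waveform given or found in stack metadata.",
                 class = "octflow_error_config")
  }
  n <- config$refractive_index
  if (is.null(n) && !is.null(stack$meta$geom)) {
    n <- stack$meta$geom$refractive_index_n
  }
  if (is.null(n)) n <- 1.45

  st <- discard_startup(stack, config$discard_time)
  st <- upsample_lateral(st, config$upsample, config$upsample_method)
  plates <- detect_plates(st)
  flat <- flatten_tilt(st, plates, n = n, parallel_tol = config$parallel_tol)
  grid <- partition_grid(flat)
  thresholds <- threshold_rows(flat, grid, config$threshold_k)
  validity <- build_validity(flat, grid, thresholds)
  dfac <- distortion_factors(n, flat$measured_alpha)
  dt <- frame_interval(flat)
  # depths for the regression: where the tracers actually are
  grid_eff <- grid
  grid_eff$depth_um <- effective_depths(flat, grid, thresholds, validity)
  p_target <- if (is.null(config$p_target)) 2L * grid$upsample
              else config$p_target

  if (waveform$kind == "triangle") {
    keep <- pad_turnarounds(flat$time, waveform, dt, config$pad_frames)
    plan <- plan_decimation_constant(flat, grid, thresholds, validity,
                                     waveform, p_target, keep)
    field <- measure_displacements(flat, grid, thresholds, validity, plan,
                                   waveform, keep, config$search_z)
    profile <- velocities_constant(field, grid_eff, flat$pixel_size_x,
                                   dfac$transverse, dt)
    theory <- shear_rate_constant(waveform$plate_speed, flat$measured_H)
    sigma_eff <- sqrt(profile$sd_um_s^2 + profile$quant_um_s^2)
    shear <- fit_shear_rate(profile$depth_um, profile$speed_um_s,
                            sigma_eff, theory = theory,
                            through_origin = config$through_origin)
    out <- list(mode = "constant", profile = profile, shear = shear,
                row_fits = NULL, waveforms = NULL)
  } else {
    plan <- plan_decimation_sinusoidal(flat, grid, thresholds, validity,
                                       waveform, p_target)
    keep <- rep(TRUE, n_frames(flat))
    field <- measure_displacements(flat, grid, thresholds, validity, plan,
                                   waveform, keep, config$search_z)
    wavs <- velocities_sinusoidal(field, grid_eff, flat$pixel_size_x,
                                  dfac$transverse, dt,
                                  omega = 2 * pi * waveform$frequency)
    phase_expected <- waveform$phase -
      2 * pi * waveform$frequency * waveform$mechanical_delay
    fits <- list()
    for (i in sort(unique(wavs$i))) {
      sub <- wavs[wavs$i == i, ]
      # per-sample spread floored by the integer-localization error
      sd_eff <- sqrt(ifelse(is.na(sub$sd_um_s), 0, sub$sd_um_s)^2 +
                       sub$quant_um_s^2)
      ft <- tryCatch(
        fit_sinusoid(sub$t, sub$v_um_s, sd_eff,
                     f0 = waveform$frequency,
                     phase_expected = phase_expected),
        octflow_error_fit = function(e) NULL)
      if (!is.null(ft)) {
        fits[[length(fits) + 1]] <- tibble::tibble(
          i = i, depth_um = sub$depth_um[1],
          amplitude = ft$amplitude, amplitude_se = ft$amplitude_se,
          frequency = ft$frequency, frequency_se = ft$frequency_se,
          phase_rel_deg = ft$phase_rel_deg,
          phase_se_deg = ft$phase_se * 180 / pi,
          r_squared = ft$r_squared, n = ft$n)
      }
    }
    row_fits <- dplyr::bind_rows(fits)
    if (nrow(row_fits) < 3) {
      rlang::abort("Fewer than 3 rows produced a sinusoid fit.",
                   class = "octflow_error_fit")
    }
    # amplitude error floor from integer peak localization (+/- 0.5 px
    # uniform, sd 0.289 px over the row's typical decimation): the fit SE
    # alone understates systematic quantization error and would let single
    # rows dominate the depth regression
    dk_row <- field |>
      dplyr::group_by(.data$i) |>
      dplyr::summarise(dk_mean = mean(.data$dk), .groups = "drop")
    quant <- convert_units(0.5 / sqrt(3) / dk_row$dk_mean,
                           flat$pixel_size_x, dfac$transverse, dt)
    profile <- tibble::tibble(
      i = row_fits$i, depth_um = row_fits$depth_um,
      speed_um_s = row_fits$amplitude, sd_um_s = row_fits$amplitude_se,
      quant_um_s = quant[match(row_fits$i, dk_row$i)],
      n_meas = row_fits$n)
    theory <- shear_rate_amplitude(waveform$peak_speed, flat$measured_H)
    sigma_eff <- sqrt(profile$sd_um_s^2 + profile$quant_um_s^2)
    shear <- fit_shear_rate(profile$depth_um, profile$speed_um_s,
                            sigma_eff, theory = theory,
                            through_origin = config$through_origin)
    wmean <- function(x, se) {
      w <- 1 / se^2
      w[!is.finite(w)] <- stats::median(w[is.finite(w)], na.rm = TRUE)
      if (all(!is.finite(w))) w <- rep(1, length(x))
      c(stats::weighted.mean(x, w), sqrt(1 / sum(w)))
    }
    fq <- wmean(row_fits$frequency, row_fits$frequency_se)
    ph <- wmean(row_fits$phase_rel_deg, row_fits$phase_se_deg)
    out <- list(mode = "sinusoidal", profile = profile, shear = shear,
                row_fits = row_fits, waveforms = wavs,
                frequency = fq[1], frequency_se = fq[2],
                phase_deg = ph[1], phase_se_deg = ph[2])
  }
  out$displacements <- field
  out$measured_H <- flat$measured_H
  out$measured_alpha <- flat$measured_alpha
  out$plate_angles <- flat$plate_angles
  out$thresholds <- thresholds
  out$validity <- validity
  out$plan <- plan
  out$grid <- grid
  out$config <- config
  out$waveform <- waveform
  out$theory <- out$shear$theory
  structure(out, class = "oct_ptv_result")
}

#' @export
print.oct_ptv_result <- function(x, ...) {
  cat(sprintf("<oct_ptv_result> %s drive, measured H = %.1f um (tilt %.2f deg)\n",
              x$mode, x$measured_H, x$measured_alpha))
  print(x$shear)
  if (x$mode == "sinusoidal") {
    cat(sprintf("  frequency %.4g +/- %.2g Hz, phase %.3g +/- %.2g deg\n",
                x$frequency, x$frequency_se, x$phase_deg, x$phase_se_deg))
  }
  invisible(x)
}

#' @export
glance.oct_ptv_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    shear_rate = x$shear$shear_rate,
    shear_rate_se = x$shear$se,
    shear_rate_theory = x$theory,
    r.squared = x$shear$r_squared,
    frequency = if (x$mode == "sinusoidal") x$frequency else NA_real_,
    phase_deg = if (x$mode == "sinusoidal") x$phase_deg else NA_real_,
    measured_H = x$measured_H,
    n_rows = nrow(x$profile))
}

#' @export
tidy.oct_ptv_result <- function(x, ...) x$profile
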