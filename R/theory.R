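#' Fluid properties
#'
#' Bundle of the physical properties of the working fluid needed by the flow
#' theory: dynamic viscosity, mass density, refractive index and (optionally)
#' the water/glycerol weight fractions it was mixed from.
#'
#' @param dynamic_viscosity Dynamic viscosity in mPa s (1 mPa s = 1 cP).
#' @param density Mass density in kg/m^3.
#' @param refractive_index Refractive index (>= 1). If `NULL` and the weight
#'   fractions are given, it is computed with [arago_biot_index()].
#' @param water_weight_fraction,glycerol_weight_fraction Weight fractions in
#'   `[0, 1]`; when both are given they must sum to 1.
#'
#' @return An object of class `fluid_properties` (a named list).
#' @examples
#' fluid_properties(400, 1180, water_weight_fraction = 0.16,
#'                  glycerol_weight_fraction = 0.84)
#' @export
fluid_properties <- function(dynamic_viscosity, density,
                             refractive_index = NULL,
                             water_weight_fraction = NULL,
                             glycerol_weight_fraction = NULL) {
  stopifnot(is.numeric(dynamic_viscosity), length(dynamic_viscosity) == 1)
  if (dynamic_viscosity <= 0) rlang::abort("`dynamic_viscosity` must be > 0.",
                                           class = "octflow_error_domain")
  if (density <= 0) rlang::abort("`density` must be > 0.",
                                 class = "octflow_error_domain")
  if (!is.null(water_weight_fraction) && !is.null(glycerol_weight_fraction)) {
    if (is.null(refractive_index)) {
      refractive_index <- arago_biot_index(water_weight_fraction,
                                           glycerol_weight_fraction)
    }
  }
  if (!is.null(refractive_index) && refractive_index < 1) {
    rlang::abort("`refractive_index` must be >= 1.",
                 class = "octflow_error_domain")
  }
  structure(
    list(dynamic_viscosity = dynamic_viscosity,
         density = density,
         refractive_index = refractive_index,
         water_weight_fraction = water_weight_fraction,
         glycerol_weight_fraction = glycerol_weight_fraction),
    class = "fluid_properties")
}

#' Chamber geometry
#'
#' Geometry of the microparallel-plate chamber: plate separation `H`, tilt of
#' the chamber relative to the imaging axis, and the refractive index used for
#' depth calibration. Depth `z` is measured downward from the stationary top
#' plate (`z = 0`) to the driven bottom plate (`z = H`).
#'
#' @param separation_H Plate separation in micrometers.
#' @param tilt_alpha Tilt angle from horizontal, degrees (|alpha| < 90).
#' @param refractive_index_n Sample refractive index (>= 1).
#'
#' @return An object of class `chamber_geometry`.
#' @examples
#' chamber_geometry(292, tilt_alpha = 2, refractive_index_n = 1.45)
#' @export
chamber_geometry <- function(separation_H, tilt_alpha = 0,
                             refractive_index_n = 1.45) {
  if (separation_H <= 0) rlang::abort("`separation_H` must be > 0.",
                                      class = "octflow_error_domain")
  if (abs(tilt_alpha) >= 90) rlang::abort("|tilt_alpha| must be < 90 degrees.",
                                          class = "octflow_error_domain")
  if (refractive_index_n < 1) rlang::abort("`refractive_index_n` must be >= 1.",
                                           class = "octflow_error_domain")
  structure(
    list(separation_H = separation_H,
         tilt_alpha = tilt_alpha,
         refractive_index_n = refractive_index_n),
    class = "chamber_geometry")
}

#' Driving waveform of the bottom plate
#'
#' Lateral motion law of the driven bottom plate. A `triangle` waveform moves
#' the plate at a constant speed `+/- Vx0`, reversing every half period
#' (constant shear rate in each sweep); a `sinusoid` waveform oscillates it
#' with velocity amplitude `Ux0` (oscillatory shear). Displacement amplitudes
#' are peak-to-peak throughout.
#'
#' For a triangle, the plate covers the full peak-to-peak travel once per half
#' period, so `Vx0 = 2 * frequency * peak_to_peak`. For a sinusoid with
#' displacement `(peak_to_peak / 2) * sin(w t + phi)`, the velocity amplitude
#' is `Ux0 = pi * frequency * peak_to_peak`.
#'
#' @param kind `"triangle"` or `"sinusoid"`.
#' @param frequency Driving frequency in Hz (> 0).
#' @param peak_to_peak Peak-to-peak plate displacement in micrometers. Exactly
#'   one of `peak_to_peak` and `plate_speed`/`peak_speed` must be given.
#' @param plate_speed Triangle plate speed `Vx0` in um/s.
#' @param peak_speed Sinusoid velocity amplitude `Ux0` in um/s.
#' @param phase Phase `phi` of the sinusoid in radians (at the start of plate
#'   motion). Ignored for the triangle.
#' @param mechanical_delay Delay in seconds between the acquisition trigger
#'   and the actual start of plate motion. Defaults to 9 ms, the measured lag
#'   of the actuation stage.
#'
#' @return An object of class `driving_waveform` with fields `kind`,
#'   `frequency`, `peak_to_peak`, `plate_speed` (triangle) or `peak_speed`
#'   (sinusoid), `phase`, `mechanical_delay`.
#' @examples
#' driving_waveform("triangle", frequency = 0.5, plate_speed = 60)
#' driving_waveform("sinusoid", frequency = 10, peak_to_peak = 24)
#' @export
driving_waveform <- function(kind = c("triangle", "sinusoid"),
                             frequency,
                             peak_to_peak = NULL,
                             plate_speed = NULL,
                             peak_speed = NULL,
                             phase = 0,
                             mechanical_delay = 0.009) {
  kind <- match.arg(kind)
  if (frequency <= 0) rlang::abort("`frequency` must be > 0.",
                                   class = "octflow_error_domain")
  if (kind == "triangle") {
    if (is.null(plate_speed) && is.null(peak_to_peak)) {
      rlang::abort("Give `plate_speed` or `peak_to_peak` for a triangle.",
                   class = "octflow_error_config")
    }
    if (is.null(plate_speed)) plate_speed <- 2 * frequency * peak_to_peak
    if (is.null(peak_to_peak)) peak_to_peak <- plate_speed / (2 * frequency)
    out <- list(kind = kind, frequency = frequency,
                peak_to_peak = peak_to_peak, plate_speed = plate_speed,
                phase = 0, mechanical_delay = mechanical_delay)
  } else {
    if (is.null(peak_speed) && is.null(peak_to_peak)) {
      rlang::abort("Give `peak_speed` or `peak_to_peak` for a sinusoid.",
                   class = "octflow_error_config")
    }
    if (is.null(peak_speed)) peak_speed <- pi * frequency * peak_to_peak
    if (is.null(peak_to_peak)) peak_to_peak <- peak_speed / (pi * frequency)
    out <- list(kind = kind, frequency = frequency,
                peak_to_peak = peak_to_peak, peak_speed = peak_speed,
                phase = phase, mechanical_delay = mechanical_delay)
  }
  structure(out, class = "driving_waveform")
}

# Bottom-plate velocity at time t (um/s). The plate is at rest until the
# mechanical delay has elapsed; thereafter the waveform is periodic.
plate_velocity <- function(t, waveform) {
  tau <- t - waveform$mechanical_delay
  f <- waveform$frequency
  if (waveform$kind == "triangle") {
    # +Vx0 on [0, T/4) and [3T/4, T); -Vx0 on (T/4, 3T/4)
    ph <- (tau * f) %% 1
    v <- ifelse(ph < 0.25 | ph >= 0.75, waveform$plate_speed,
                -waveform$plate_speed)
  } else {
    v <- waveform$peak_speed * cos(2 * pi * f * tau + waveform$phase)
  }
  ifelse(tau < 0, 0, v)
}

#' Bottom-plate lateral position
#'
#' Time integral of the driving velocity: a zero-mean zig-zag for the triangle
#' waveform and `(peak_to_peak / 2) * sin(w t + phi)` for the sinusoid, both
#' shifted by the mechanical delay (the plate is at rest before the delay has
#' elapsed).
#'
#' @param t Time(s) in seconds since the acquisition trigger.
#' @param waveform A [driving_waveform()].
#' @return Lateral plate displacement(s) in micrometers.
#' @examples
#' wf <- driving_waveform("triangle", frequency = 0.5, plate_speed = 60)
#' plate_position(c(0, 0.509, 1.009), wf)
#' @export
plate_position <- function(t, waveform) {
  tau <- pmax(t - waveform$mechanical_delay, 0)
  f <- waveform$frequency
  if (waveform$kind == "triangle") {
    amp <- waveform$peak_to_peak / 2
    ph <- (tau * f) %% 1
    x <- ifelse(ph < 0.25, waveform$plate_speed * ph / f,
         ifelse(ph < 0.75, amp - waveform$plate_speed * (ph - 0.25) / f,
                -amp + waveform$plate_speed * (ph - 0.75) / f))
  } else {
    amp <- waveform$peak_to_peak / 2
    # integral of Ux0 cos(w tau + phi), anchored so position is zero-mean
    x <- amp * sin(2 * pi * f * tau + waveform$phase)
  }
  x
}

#' Couette velocity profile between the plates
#'
#' Closed-form low-Reynolds velocity of a Newtonian fluid between parallel
#' plates with the bottom plate driven laterally: the velocity is linear in
#' depth, zero at the stationary top plate and equal to the plate velocity at
#' the driven plate. For a triangle drive this is the steady constant-shear
#' solution in each sweep; for a sinusoid the profile oscillates in phase with
#' the drive (no phase lag in the low-Reynolds, gap-loading limit).
#'
#' @param z Depth(s) from the top plate in micrometers, in `[0, H]`.
#' @param t Time(s) in seconds.
#' @param waveform A [driving_waveform()].
#' @param geom A [chamber_geometry()].
#' @return Lateral fluid velocity in um/s (sign follows the sweep direction).
#' @examples
#' wf <- driving_waveform("triangle", frequency = 0.5, plate_speed = 60)
#' gm <- chamber_geometry(292)
#' couette_velocity(c(0, 146, 292), t = 0.1, wf, gm)
#' @export
couette_velocity <- function(z, t, waveform, geom) {
  H <- geom$separation_H
  if (any(z < 0 | z > H)) {
    rlang::abort("`z` must lie in [0, H].", class = "octflow_error_domain")
  }
  (z / H) * plate_velocity(t, waveform)
}

#' Constant shear rate of a triangle-driven chamber
#'
#' The depth gradient of the linear Couette profile: `Vx0 / H`, constant in
#' depth during each sweep.
#'
#' @param Vx0 Plate speed in um/s.
#' @param H Plate separation in micrometers (> 0).
#' @return Shear rate in 1/s.
#' @examples
#' shear_rate_constant(60, 292) # ~0.21 1/s
#' @export
shear_rate_constant <- function(Vx0, H) {
  if (any(H <= 0)) rlang::abort("`H` must be > 0.",
                                class = "octflow_error_domain")
  Vx0 / H
}

#' Shear-rate amplitude of a sinusoid-driven chamber
#'
#' The depth gradient of the oscillating velocity amplitude: `Ux0 / H`,
#' constant in depth.
#'
#' @param Ux0 Plate velocity amplitude in um/s.
#' @param H Plate separation in micrometers (> 0).
#' @return Shear-rate amplitude in 1/s.
#' @examples
#' shear_rate_amplitude(pi * 10 * 24, 150) # ~5.0 1/s
#' @export
shear_rate_amplitude <- function(Ux0, H) {
  if (any(H <= 0)) rlang::abort("`H` must be > 0.",
                                class = "octflow_error_domain")
  Ux0 / H
}

#' Peak speed of a sinusoidally driven plate
#'
#' For displacement `(peak_to_peak / 2) * sin(2 pi f t)`, the velocity
#' amplitude is `pi * f * peak_to_peak`.
#'
#' @param frequency Driving frequency in Hz (>= 0).
#' @param peak_to_peak Peak-to-peak displacement in micrometers (>= 0).
#' @return Peak plate speed in um/s.
#' @examples
#' peak_speed_sinusoid(10, 24) # ~754 um/s
#' @export
peak_speed_sinusoid <- function(frequency, peak_to_peak) {
  if (any(frequency < 0) || any(peak_to_peak < 0)) {
    rlang::abort("Inputs must be >= 0.", class = "octflow_error_domain")
  }
  pi * frequency * peak_to_peak
}

#' Peak-to-peak shear strain of a triangle drive
#'
#' The plate travels `Vx0 / (2 f)` per half period; dividing by the plate
#' separation gives the peak-to-peak shear strain (dimensionless; multiply by
#' 100 for percent).
#'
#' @param Vx0 Plate speed in um/s.
#' @param frequency Driving frequency in Hz (> 0).
#' @param H Plate separation in micrometers (> 0).
#' @return Peak-to-peak strain (dimensionless).
#' @examples
#' peak_to_peak_strain_triangle(60, 0.5, 300) # 0.20 = 20%
#' @export
peak_to_peak_strain_triangle <- function(Vx0, frequency, H) {
  if (any(frequency <= 0) || any(H <= 0)) {
    rlang::abort("`frequency` and `H` must be > 0.",
                 class = "octflow_error_domain")
  }
  Vx0 / (2 * frequency * H)
}

#' Viscous transient time of the fluid layer
#'
#' Viscous diffusion time `H^2 / nu = H^2 rho / mu` across the gap: the time
#' for the linear Couette profile to establish after a change in plate
#' velocity. For the viscous fluids and thin gaps this chamber targets it is
#' well under a millisecond, so steady-state profiles can be assumed frame to
#' frame.
#'
#' @param H Plate separation in micrometers (> 0).
#' @param fluid A [fluid_properties()].
#' @return Transient time in seconds.
#' @examples
#' transient_time(300, fluid_properties(294, 1185)) # < 1e-3 s
#' @export
transient_time <- function(H, fluid) {
  if (any(H < 0)) rlang::abort("`H` must be >= 0.",
                               class = "octflow_error_domain")
  H_m <- H * 1e-6
  mu_pa_s <- fluid$dynamic_viscosity * 1e-3
  H_m^2 * fluid$density / mu_pa_s
}

#' Arago-Biot refractive index of a water-glycerol mixture
#'
#' Weight-fraction-weighted sum of the component indices, 1.340 for water and
#' 1.465 for glycerol.
#'
#' @param water_fraction,glycerol_fraction Weight fractions summing to 1.
#' @return Refractive index of the mixture.
#' @examples
#' arago_biot_index(0.16, 0.84)
#' @export
arago_biot_index <- function(water_fraction, glycerol_fraction) {
  if (any(water_fraction < 0) || any(glycerol_fraction < 0)) {
    rlang::abort("Fractions must be >= 0.", class = "octflow_error_domain")
  }
  if (any(abs(water_fraction + glycerol_fraction - 1) > 1e-9)) {
    rlang::abort("Weight fractions must sum to 1.",
                 class = "octflow_error_validation")
  }
  1.340 * water_fraction + 1.465 * glycerol_fraction
}

#' Reynolds number of the sheared layer
#'
#' Convenience estimate `Re = rho * V * H / mu` with the plate speed as the
#' velocity scale and the plate separation as the length scale. Alternative
#' characteristic scales are in use in the literature; this one is exposed
#' only to confirm that inertia is negligible (Re << 1).
#'
#' @param speed Characteristic speed in um/s.
#' @param H Plate separation in micrometers.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(speed, H, fluid) {
  fluid$density * (speed * 1e-6) * (H * 1e-6) / (fluid$dynamic_viscosity * 1e-3)
}

#' Operating-point summary for a configuration
#'
#' One-row tibble of the analytic operating point implied by a waveform,
#' geometry and fluid: shear rate (triangle) or shear-rate amplitude
#' (sinusoid), peak plate speed, peak-to-peak strain, viscous transient time
#' and Reynolds number.
#'
#' @param waveform A [driving_waveform()].
#' @param geom A [chamber_geometry()].
#' @param fluid A [fluid_properties()], or `NULL` to omit the fluid-dependent
#'   quantities.
#' @return A tibble with one row.
#' @examples
#' operating_point(driving_waveform("sinusoid", 10, peak_to_peak = 24),
#'                 chamber_geometry(150))
#' @export
operating_point <- function(waveform, geom, fluid = NULL) {
  H <- geom$separation_H
  if (waveform$kind == "triangle") {
    v <- waveform$plate_speed
    rate <- shear_rate_constant(v, H)
  } else {
    v <- waveform$peak_speed
    rate <- shear_rate_amplitude(v, H)
  }
  strain <- waveform$peak_to_peak / H
  tibble::tibble(
    kind = waveform$kind,
    frequency_hz = waveform$frequency,
    separation_um = H,
    peak_speed_um_s = v,
    shear_rate_s1 = rate,
    peak_to_peak_strain = strain,
    transient_time_s = if (is.null(fluid)) NA_real_ else transient_time(H, fluid),
    reynolds = if (is.null(fluid)) NA_real_ else reynolds_number(v, H, fluid))
}
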