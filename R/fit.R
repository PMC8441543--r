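wrap_pi <- function(x) {
  # wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Fit a sinusoid to a velocity waveform
#'
#' Non-linear least squares fit of `A * cos(2 pi f t + phi)` to velocity
#' samples, weighted by inverse variance when per-sample standard deviations
#' are available (standard deviations are floored at 1e-6 of the amplitude
#' scale to avoid infinite weights; samples without a spread, e.g. rows with
#' a single valid ROI, receive the median weight, or unit weight if no
#' spread exists at all). The fit is initialized from the driving frequency
#' and a linear cos/sin regression at that frequency. A negative fitted
#' amplitude is folded into the phase, so `A >= 0` and `phi` is wrapped to
#' `(-pi, pi]`.
#'
#' @param t Sample times in seconds.
#' @param v Velocity samples (um/s).
#' @param sd Optional per-sample standard deviations (um/s); `NA` allowed.
#' @param f0 Initial frequency in Hz (the driving frequency).
#' @param phase_expected Phase (radians, at `t = 0`) of the driving velocity
#'   waveform, i.e. `phi_drive - 2 pi f0 * mechanical_delay`; the reported
#'   relative phase (`phase_rel_deg`) is the fitted phase minus this,
#'   wrapped to `(-180, 180]` degrees.
#' @return An object of class `sinusoid_fit` with fields `amplitude`,
#'   `amplitude_se`, `frequency`, `frequency_se`, `phase`, `phase_se`
#'   (radians), `phase_rel_deg`, `r_squared`, `n`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' f <- fit_sinusoid(t, 10 * cos(2 * pi * 3 * t), f0 = 3)
#' f$amplitude; f$frequency
#' @export
fit_sinusoid <- function(t, v, sd = NULL, f0, phase_expected = 0) {
  ok <- is.finite(t) & is.finite(v)
  t <- t[ok]; v <- v[ok]
  if (!is.null(sd)) sd <- sd[ok]
  if (length(v) < 4 || diff(range(t)) < 1 / f0) {
    rlang::abort("Need >= 4 samples spanning at least one period.",
                 class = "octflow_error_fit")
  }
  amp_scale <- max(abs(v), 1e-12)
  w <- rep(1, length(v))
  if (!is.null(sd) && any(is.finite(sd) & sd > 0)) {
    sdf <- pmax(sd, 1e-6 * amp_scale)
    w <- 1 / sdf^2
    w[!is.finite(w)] <- NA
    med <- stats::median(w, na.rm = TRUE)
    w[is.na(w)] <- med
  }
  # linear initialization at the driving frequency
  cc <- cos(2 * pi * f0 * t); ss <- sin(2 * pi * f0 * t)
  lin <- stats::lm(v ~ 0 + cc + ss, weights = w)
  a <- stats::coef(lin)[["cc"]]; b <- stats::coef(lin)[["ss"]]
  A0 <- max(sqrt(a^2 + b^2), 1e-9 * amp_scale)
  phi0 <- atan2(-b, a)
  rss_lin <- sum(w * stats::resid(lin)^2)
  if (rss_lin <= 1e-18 * sum(w * v^2)) {
    # data lie exactly on the initialization: nothing left to refine
    return(structure(
      list(amplitude = A0, amplitude_se = 0,
           frequency = f0, frequency_se = 0,
           phase = wrap_pi(phi0), phase_se = 0,
           phase_rel_deg = wrap_pi(phi0 - phase_expected) * 180 / pi,
           r_squared = 1, n = length(v)),
      class = "sinusoid_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * cos(2 * pi * f * t + phi),
      start = list(A = A0, f = f0, phi = phi0),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      rlang::abort(paste0("Sinusoid fit did not converge: ",
                          conditionMessage(e)),
                   class = "octflow_error_fit")
    })
  est <- summary(fit)$coefficients
  A <- est["A", "Estimate"]; f <- est["f", "Estimate"]
  phi <- est["phi", "Estimate"]
  if (A < 0) {
    A <- -A
    phi <- phi + pi
  }
  phi <- wrap_pi(phi)
  res <- stats::resid(fit)
  r2 <- 1 - sum(w * res^2) / sum(w * (v - stats::weighted.mean(v, w))^2)
  structure(
    list(amplitude = A, amplitude_se = est["A", "Std. Error"],
         frequency = f, frequency_se = est["f", "Std. Error"],
         phase = phi, phase_se = est["phi", "Std. Error"],
         phase_rel_deg = wrap_pi(phi - phase_expected) * 180 / pi,
         r_squared = r2, n = length(v)),
    class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_fit> A = %.4g +/- %.2g um/s, f = %.4g +/- %.2g Hz, phase = %.3g deg (R2 = %.4f, n = %d)\n",
    x$amplitude, x$amplitude_se, x$frequency, x$frequency_se,
    x$phase_rel_deg, x$r_squared, x$n))
  invisible(x)
}

#' Shear rate by weighted regression of velocity on depth
#'
#' Weighted least-squares regression of row velocity (or velocity amplitude)
#' on depth below the top plate; the slope is the shear rate (amplitude).
#' Weights are inverse variances `1 / sigma^2`; rows without a usable spread
#' (zero, `NA`, or a single measurement) receive the median of the available
#' weights, and equal weights reduce the fit to ordinary least squares. The
#' intercept is left free by default.
#'
#' @param depth Row depths in micrometers (from the top plate).
#' @param value Row speeds or velocity amplitudes in um/s.
#' @param sigma Row standard deviations (um/s); `NULL` for equal weights.
#' @param theory Theoretical shear rate to attach for comparison (1/s).
#' @param through_origin If `TRUE`, force a zero intercept at the top plate.
#' @return An object of class `shear_fit` with fields `shear_rate` (slope,
#'   1/s), `se`, `intercept`, `intercept_se`, `r_squared`, `n`, `theory`,
#'   and the input `data` as a tibble.
#' @examples
#' z <- c(30, 90, 150, 210, 270)
#' fit_shear_rate(z, 0.21 * z, theory = 0.21)
#' @export
fit_shear_rate <- function(depth, value, sigma = NULL, theory = NA_real_,
                           through_origin = FALSE) {
  ok <- is.finite(depth) & is.finite(value)
  depth <- depth[ok]; value <- value[ok]
  if (!is.null(sigma)) sigma <- sigma[ok]
  if (length(depth) < 3) {
    rlang::abort("Need at least 3 depth rows for the shear-rate regression.",
                 class = "octflow_error_fit")
  }
  w <- rep(1, length(depth))
  if (!is.null(sigma)) {
    w <- 1 / sigma^2
    good <- is.finite(w) & w > 0
    if (any(good)) {
      w[!good] <- stats::median(w[good])
    } else {
      w <- rep(1, length(depth))
    }
  }
  fit <- if (through_origin) stats::lm(value ~ 0 + depth, weights = w)
         else stats::lm(value ~ depth, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  slope <- co["depth", "Estimate"]
  structure(
    list(shear_rate = slope,
         se = co["depth", "Std. Error"],
         intercept = if (through_origin) 0 else co["(Intercept)", "Estimate"],
         intercept_se = if (through_origin) NA_real_
                        else co["(Intercept)", "Std. Error"],
         r_squared = sm$r.squared,
         n = length(depth),
         theory = theory,
         data = tibble::tibble(depth_um = depth, value = value,
                               sigma = if (is.null(sigma)) NA_real_
                                       else sigma,
                               weight = w)),
    class = "shear_fit")
}

#' @export
print.shear_fit <- function(x, ...) {
  cat(sprintf(
    "<shear_fit> shear rate = %.4g +/- %.2g 1/s (R2 = %.4f, n = %d rows)\n",
    x$shear_rate, x$se, x$r_squared, x$n))
  if (is.finite(x$theory)) {
    cat(sprintf("  theory: %.4g 1/s (difference %+.2f%%)\n", x$theory,
                100 * (x$shear_rate - x$theory) / x$theory))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.shear_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "depth"),
    estimate = c(x$intercept, x$shear_rate),
    std.error = c(x$intercept_se, x$se))
}

#' @export
glance.shear_fit <- function(x, ...) {
  tibble::tibble(shear_rate = x$shear_rate, se = x$se,
                 r.squared = x$r_squared, n = x$n, theory = x$theory)
}

#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "frequency", "phase"),
    estimate = c(x$amplitude, x$frequency, x$phase),
    std.error = c(x$amplitude_se, x$frequency_se, x$phase_se))
}

#' @export
glance.sinusoid_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, frequency = x$frequency,
                 phase_rel_deg = x$phase_rel_deg, r.squared = x$r_squared,
                 n = x$n)
}
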