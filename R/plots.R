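#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tracked velocity profile with its shear-rate fit
#'
#' Velocity (amplitude) versus depth with error bars, the weighted
#' regression line, and the theoretical Couette line when available.
#'
#' @param object An `oct_ptv_result` from [track_stack()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oct_ptv_result <- function(object, ...) {
  pr <- object$profile
  sh <- object$shear
  p <- ggplot2::ggplot(pr, ggplot2::aes(x = .data$depth_um,
                                        y = .data$speed_um_s)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$speed_um_s - .data$sd_um_s,
                                        ymax = .data$speed_um_s + .data$sd_um_s),
                           width = 0, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = sh$shear_rate, intercept = sh$intercept,
                         color = "steelblue") +
    ggplot2::labs(
      x = "Depth below top plate (µm)",
      y = if (object$mode == "constant") "Speed (µm/s)"
          else "Velocity amplitude (µm/s)",
      title = sprintf("Shear rate %.3g ± %.2g 1/s (R² = %.3f)",
                      sh$shear_rate, sh$se, sh$r_squared)) +
    ggplot2::theme_minimal()
  if (is.finite(sh$theory)) {
    p <- p + ggplot2::geom_abline(slope = sh$theory, intercept = 0,
                                  linetype = "dashed", color = "grey30")
  }
  p
}

#' Plot per-depth velocity waveforms
#'
#' Sinusoidal-mode velocity samples versus time, one trace per ROI depth,
#' offset vertically for clarity.
#'
#' @param result An `oct_ptv_result` in sinusoidal mode.
#' @param offset Vertical offset between depth traces (um/s); defaults to
#'   1.2x the largest amplitude.
#' @return A ggplot object.
#' @export
plot_waveforms <- function(result, offset = NULL) {
  if (is.null(result$waveforms)) {
    rlang::abort("No waveforms: result is not from a sinusoidal drive.",
                 class = "octflow_error_config")
  }
  w <- result$waveforms
  if (is.null(offset)) offset <- 1.2 * max(abs(w$v_um_s))
  w$trace <- w$v_um_s + offset * (match(w$i, sort(unique(w$i))) - 1)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$t, y = .data$trace,
                                  group = .data$i,
                                  color = .data$depth_um)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Time (s)", y = "Velocity + offset (µm/s)",
                  color = "Depth (µm)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of measured versus theoretical quantities
#'
#' Percent difference against the pair mean, with the bias (solid), its 95%
#' confidence interval (dotted) and the limits of agreement (dashed).
#'
#' @param object A [bland_altman()] object.
#' @param pair_mean Optional x coordinates (pair means); indices otherwise.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, pair_mean = NULL, ...) {
  x <- if (is.null(pair_mean)) seq_along(object$diffs) else pair_mean
  df <- tibble::tibble(x = x, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$bias, color = "black") +
    ggplot2::geom_hline(yintercept = c(object$ci_low, object$ci_high),
                        color = "red", linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        color = "black", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = if (is.null(pair_mean)) "Experiment"
                      else "Mean of measured and theory",
                  y = "Difference (%)") +
    ggplot2::theme_minimal()
}
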