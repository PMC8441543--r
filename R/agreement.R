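#' Percent difference between a measurement and its reference
#'
#' Differences between measured and theoretical values are expressed as
#' percentages. By default the theoretical value is the denominator (theory
#' is the reference standard); `percent_of = "mean"` uses the classical
#' Bland-Altman pair-mean denominator instead.
#'
#' @param measured,theoretical Numeric vectors.
#' @param percent_of `"theory"` (default) or `"mean"`.
#' @return Percent differences, `100 * (measured - theoretical) / denom`.
#' @examples
#' percent_difference(0.22, 0.21)
#' @export
percent_difference <- function(measured, theoretical,
                               percent_of = c("theory", "mean")) {
  percent_of <- match.arg(percent_of)
  denom <- if (percent_of == "theory") theoretical
           else (measured + theoretical) / 2
  if (any(denom == 0)) {
    rlang::abort("Zero reference value in percent difference.",
                 class = "octflow_error_domain")
  }
  100 * (measured - theoretical) / denom
}

#' Bland-Altman statistics of a difference vector
#'
#' Mean difference (bias), 95% limits of agreement `bias +/- 1.96 SD` and
#' the 95% confidence interval of the bias `bias +/- 1.96 SD / sqrt(n)`,
#' with the sample (n - 1) standard deviation and the conventional normal
#' multiplier.
#'
#' @param diffs Numeric vector of (percent) differences, length >= 2.
#' @return An object of class `bland_altman` (also a named list): `n`,
#'   `bias`, `ci_low`, `ci_high`, `loa_low`, `loa_high`, `sd`, and the input
#'   `diffs`.
#' @examples
#' bland_altman(c(-2, 0, 2))
#' @export
bland_altman <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 2) {
    rlang::abort("Bland-Altman statistics need at least 2 differences.",
                 class = "octflow_error_domain")
  }
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(
    list(n = n, bias = bias,
         ci_low = bias - 1.96 * s / sqrt(n),
         ci_high = bias + 1.96 * s / sqrt(n),
         loa_low = bias - 1.96 * s,
         loa_high = bias + 1.96 * s,
         sd = s, diffs = diffs),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d: bias %.3g%% (95%% CI %.3g to %.3g), LoA %.3g to %.3g\n",
    x$n, x$bias, x$ci_low, x$ci_high, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, ci_low = x$ci_low,
                 ci_high = x$ci_high, loa_low = x$loa_low,
                 loa_high = x$loa_high, sd = x$sd)
}

#' Compare a set of experiments against theory
#'
#' Takes a data frame with one row per experiment holding measured and
#' theoretical values of one or more quantities (e.g. shear rate, frequency,
#' phase) and returns, per quantity, the percent differences, their
#' Bland-Altman statistics and the scatter coordinates (pair mean vs percent
#' difference).
#'
#' @param experiments A data frame with columns `<q>_measured` and
#'   `<q>_theory` for each quantity `q` in `quantities`. At least 2 rows.
#' @param quantities Character vector of quantity prefixes to analyse.
#' @param percent_of Denominator convention, see [percent_difference()].
#' @return A list with `table` (the input plus `<q>_pct_diff` columns) and
#'   `stats`, a named list of [bland_altman()] objects per quantity.
#' @export
compare_experiments <- function(experiments,
                                quantities = "shear_rate",
                                percent_of = c("theory", "mean")) {
  percent_of <- match.arg(percent_of)
  experiments <- tibble::as_tibble(experiments)
  if (nrow(experiments) < 2) {
    rlang::abort("Need at least 2 experiments to compare.",
                 class = "octflow_error_domain")
  }
  stats_out <- list()
  for (q in quantities) {
    mcol <- paste0(q, "_measured"); tcol <- paste0(q, "_theory")
    if (!all(c(mcol, tcol) %in% names(experiments))) {
      rlang::abort(paste0("Missing columns for quantity '", q, "'."),
                   class = "octflow_error_config")
    }
    pd <- percent_difference(experiments[[mcol]], experiments[[tcol]],
                             percent_of)
    experiments[[paste0(q, "_pct_diff")]] <- pd
    experiments[[paste0(q, "_pair_mean")]] <-
      (experiments[[mcol]] + experiments[[tcol]]) / 2
    stats_out[[q]] <- bland_altman(pd)
  }
  list(table = experiments, stats = stats_out)
}
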