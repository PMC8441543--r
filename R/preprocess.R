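#' Refraction and tilt distortion factors
#'
#' Free-space pixel calibrations must be corrected for the sample refractive
#' index `n` and chamber tilt `alpha` before they measure physical distances.
#' Axial distances (optical path lengths) are multiplied by
#' `sqrt(n^2 - sin^2(alpha)) / n^2`, which reduces to the required `1 / n` at
#' normal incidence (OCT measures optical depth = n x physical depth);
#' lateral distances are multiplied by `1 / cos(alpha)` to undo the tilt
#' foreshortening.
#'
#' @param n Refractive index (>= 1).
#' @param alpha Tilt angle in degrees (|alpha| < 90).
#' @return A list with elements `axial` and `transverse`.
#' @examples
#' distortion_factors(1.45, 5)
#' @export
distortion_factors <- function(n, alpha) {
  stopifnot(n >= 1, abs(alpha) < 90)
  a <- alpha * pi / 180
  list(axial = sqrt(n^2 - sin(a)^2) / n^2,
       transverse = 1 / cos(a))
}

#' Discard acquisition start-up frames
#'
#' Drops every frame whose start time falls within the first `discard_time`
#' seconds (30 ms by default), removing stage start-up transients and the
#' mechanical lag window from the analysis. Absolute timestamps are kept so
#' later stages stay referenced to the driving waveform (which itself carries
#' the mechanical delay).
#'
#' @param stack An [oct_stack()].
#' @param discard_time Seconds to discard from the start (default 0.03).
#' @return The stack without the discarded frames.
#' @export
discard_startup <- function(stack, discard_time = 0.03) {
  keep <- stack$time >= discard_time
  if (!any(keep)) {
    rlang::abort("All frames fall inside the start-up discard window.",
                 class = "octflow_error_invalid_stack")
  }
  stack$frames <- stack$frames[, , keep, drop = FALSE]
  stack$time <- stack$time[keep]
  stack
}

# Sparse cubic-convolution (Catmull-Rom) interpolation matrix mapping n_in
# samples to n_in * factor, with clamped edges. Built once per width and
# reused for every row and frame.
cubic_upsample_matrix <- function(n_in, factor) {
  n_out <- n_in * factor
  # output sample m sits at input coordinate (m - 0.5) / factor + 0.5
  xout <- (seq_len(n_out) - 0.5) / factor + 0.5
  i0 <- floor(xout)
  t <- xout - i0
  # Keys kernel, a = -0.5; weights for samples i0-1, i0, i0+1, i0+2
  w1 <- ((-0.5 * t + 1) * t - 0.5) * t
  w2 <- ((1.5 * t - 2.5) * t) * t + 1
  w3 <- ((-1.5 * t + 2) * t + 0.5) * t
  w4 <- (0.5 * t - 0.5) * t * t
  idx <- cbind(i0 - 1, i0, i0 + 1, i0 + 2)
  idx <- pmin(pmax(idx, 1), n_in)  # clamp edges
  Matrix::sparseMatrix(
    i = rep(seq_len(n_out), 4),
    j = as.vector(idx),
    x = c(w1, w2, w3, w4),
    dims = c(n_out, n_in))
}

linear_upsample_matrix <- function(n_in, factor) {
  n_out <- n_in * factor
  xout <- (seq_len(n_out) - 0.5) / factor + 0.5
  i0 <- pmin(pmax(floor(xout), 1), n_in - 1)
  t <- pmin(pmax(xout - i0, 0), 1)
  Matrix::sparseMatrix(
    i = rep(seq_len(n_out), 2),
    j = c(i0, i0 + 1),
    x = c(1 - t, t),
    dims = c(n_out, n_in))
}

#' Upsample a stack laterally
#'
#' Interpolates each image row to `factor` times as many columns (cubic
#' convolution by default), mitigating lateral digitization noise before
#' cross-correlation: integer shifts on the upsampled grid resolve 1/factor
#' of a native pixel. The lateral pixel size is divided by `factor` and the
#' factor recorded on the stack.
#'
#' @param stack An [oct_stack()].
#' @param factor Integer upsampling factor (default 4; 1 is the identity).
#' @param method `"cubic"` (Catmull-Rom) or `"linear"`.
#' @return The upsampled stack.
#' @export
upsample_lateral <- function(stack, factor = 4L,
                             method = c("cubic", "linear")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(stack)
  n_x <- dim(stack$frames)[2]
  W <- if (method == "cubic") cubic_upsample_matrix(n_x, factor)
       else linear_upsample_matrix(n_x, factor)
  Wt <- Matrix::t(W)
  out <- array(0, c(dim(stack$frames)[1], n_x * factor, n_frames(stack)))
  for (k in seq_len(n_frames(stack))) {
    out[, , k] <- as.matrix(stack$frames[, , k] %*% Wt)
  }
  stack$frames <- out
  stack$pixel_size_x <- stack$pixel_size_x / factor
  stack$upsample <- stack$upsample * factor
  stack
}

#' Detect the plate interfaces
#'
#' Finds the two bright plate lines on the time-averaged image: per-column
#' brightest rows in the top and bottom halves, each fitted with a
#' residual-trimmed least-squares line. Returns one row per plate with slope
#' (px/px), intercept (row at column 1) and tilt angle in degrees (converted
#' through the pixel aspect ratio). Supply `override` to bypass detection
#' with user-provided lines (the manual fallback).
#'
#' @param stack An [oct_stack()].
#' @param override Optional tibble with columns `plate` ("top"/"bottom"),
#'   `slope`, `intercept`, used verbatim.
#' @param max_residual Detection-failure threshold on the trimmed-fit RMS
#'   residual in pixels (default 2).
#' @return A tibble with columns `plate`, `slope`, `intercept`, `angle_deg`,
#'   `rms_residual`.
#' @export
detect_plates <- function(stack, override = NULL, max_residual = 2) {
  px <- stack$pixel_size_x
  pz <- stack$pixel_size_z
  if (!is.null(override)) {
    out <- override
    out$angle_deg <- atan(out$slope * pz / px) * 180 / pi
    out$rms_residual <- NA_real_
    return(tibble::as_tibble(out))
  }
  avg <- apply(stack$frames, c(1, 2), mean)
  n_z <- nrow(avg)
  mid <- floor(n_z / 2)
  fit_ridge <- function(rows_range) {
    sub <- avg[rows_range, , drop = FALSE]
    ridge <- rows_range[apply(sub, 2, which.max)]
    cols <- seq_along(ridge)
    keep <- rep(TRUE, length(ridge))
    for (it in 1:3) {  # residual-trimmed refit (outliers: bright particles)
      fit <- stats::lm(ridge ~ cols, subset = keep)
      res_all <- ridge - (stats::coef(fit)[1] + stats::coef(fit)[2] * cols)
      keep <- abs(res_all) <= max(2.5 * stats::mad(res_all), 1.5)
    }
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1] + stats::coef(fit)[2]),
         rms = sqrt(mean(res_all[keep]^2)))
  }
  top <- fit_ridge(seq_len(mid))
  bot <- fit_ridge(seq(mid + 1, n_z))
  out <- tibble::tibble(
    plate = c("top", "bottom"),
    slope = c(top$slope, bot$slope),
    intercept = c(top$intercept, bot$intercept),
    rms_residual = c(top$rms, bot$rms))
  out$angle_deg <- atan(out$slope * pz / px) * 180 / pi
  if (any(out$rms_residual > max_residual)) {
    rlang::abort(
      "Plate ridge fit residual above tolerance; supply `override` lines.",
      class = "octflow_error_detection")
  }
  out[, c("plate", "slope", "intercept", "angle_deg", "rms_residual")]
}

#' Flatten plate tilt and measure the plate separation
#'
#' Shifts each image column vertically by an integer number of pixels (zero
#' padding) so the top plate becomes horizontal, checks that the two plates
#' are parallel within `parallel_tol` degrees, and measures the plate
#' separation at the center column, converting pixels to micrometers with the
#' axial distortion factor.
#'
#' @param stack An [oct_stack()].
#' @param plates Plate lines from [detect_plates()]; detected if `NULL`.
#' @param n Sample refractive index for depth calibration; taken from the
#'   stack geometry metadata if `NULL`.
#' @param parallel_tol Maximum tolerated angle difference between the plates,
#'   degrees (default 1).
#' @return A `flattened_stack`: the input stack with flattened frames plus
#'   fields `top_plate_row`, `bottom_plate_row`, `measured_H` (um),
#'   `plate_angles` (the detection table) and `axial_factor`.
#' @export
flatten_tilt <- function(stack, plates = NULL, n = NULL, parallel_tol = 1) {
  if (is.null(plates)) plates <- detect_plates(stack)
  if (is.null(n)) {
    n <- if (!is.null(stack$meta$geom)) stack$meta$geom$refractive_index_n
         else 1.45
  }
  top <- plates[plates$plate == "top", ]
  bot <- plates[plates$plate == "bottom", ]
  if (abs(top$angle_deg - bot$angle_deg) > parallel_tol) {
    rlang::abort(sprintf(
      "Plates are not parallel: angle difference %.2f deg exceeds %.2f deg.",
      abs(top$angle_deg - bot$angle_deg), parallel_tol),
      class = "octflow_error_not_parallel")
  }
  n_z <- dim(stack$frames)[1]
  n_x <- dim(stack$frames)[2]
  cols <- seq_len(n_x)
  center <- (n_x + 1) / 2
  r_top <- top$intercept + top$slope * (cols - 1)
  shifts <- round(r_top - (top$intercept + top$slope * (center - 1)))
  if (any(abs(shifts) >= n_z)) {
    rlang::abort("Tilt shift exceeds image height.",
                 class = "octflow_error_domain")
  }
  ushifts <- setdiff(unique(shifts), 0)
  if (length(ushifts) > 0) {
    for (k in seq_len(n_frames(stack))) {
      fr <- stack$frames[, , k]
      for (s in ushifts) {
        cs <- cols[shifts == s]
        new <- matrix(0, n_z, length(cs))
        if (s > 0) new[seq_len(n_z - s), ] <- fr[seq(s + 1, n_z), cs]
        else new[seq(1 - s, n_z), ] <- fr[seq_len(n_z + s), cs]
        fr[, cs] <- new
      }
      stack$frames[, , k] <- fr
    }
  }
  alpha <- top$angle_deg
  d_ax <- distortion_factors(n, alpha)$axial
  top_row <- round(top$intercept + top$slope * (center - 1))
  bot_row <- round(bot$intercept + bot$slope * (center - 1))
  if (bot_row <= top_row) {
    rlang::abort("Bottom plate not below top plate after flattening.",
                 class = "octflow_error_detection")
  }
  stack$top_plate_row <- as.integer(top_row)
  stack$bottom_plate_row <- as.integer(bot_row)
  stack$measured_H <- (bot_row - top_row) * stack$pixel_size_z * d_ax
  stack$measured_alpha <- alpha
  stack$axial_factor <- d_ax
  stack$plate_angles <- plates
  class(stack) <- c("flattened_stack", class(stack))
  stack
}
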