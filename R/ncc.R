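#' Normalized cross-correlation displacement of an ROI pair
#'
#' Computes the normalized cross-correlation coefficient
#' `rho(u, v)` between two equally sized (thresholded) ROIs over integer
#' candidate displacements `u` in `[-search_x, search_x]` and `v` in
#' `[-search_z, search_z]`:
#' mean-subtracted product sum over the ROI, normalized by the product of the
#' two ROIs' root sums of squares. The second image is extended with zeros by
#' the search extents, so content displaced out of the window cannot
#' fabricate correlation. The `(u, v)` maximizing `rho` is returned as the
#' lateral and axial displacement of the scene from `I1` to `I2`; exact ties
#' are broken toward the smallest `|u|`, then smallest `|v|`, then the
#' negative candidate, a deterministic and motion-conservative rule.
#'
#' @param I1,I2 Numeric matrices of identical dimensions (z by x).
#' @param search_x,search_z Non-negative integer search extents in pixels.
#' @return A list with `xshift` (`u`), `zshift` (`v`) and `rho` (peak
#'   correlation). A zero-variance ROI on either side raises an error of
#'   class `octflow_error_zero_variance` (the caller marks the measurement
#'   missing).
#' @examples
#' a <- matrix(rnorm(60), 6, 10)
#' ncc_displacement(a, a, 3, 2)  # (0, 0, 1)
#' @export
ncc_displacement <- function(I1, I2, search_x, search_z) {
  stopifnot(identical(dim(I1), dim(I2)), search_x >= 0, search_z >= 0)
  A <- I1 - mean(I1)
  B <- I2 - mean(I2)
  s1 <- sqrt(sum(A^2))
  s2 <- sqrt(sum(B^2))
  if (s1 == 0 || s2 == 0) {
    rlang::abort("Zero-variance ROI: correlation undefined.",
                 class = "octflow_error_zero_variance")
  }
  n_z <- nrow(A); n_x <- ncol(A)
  P <- matrix(0, n_z + 2 * search_z, n_x + 2 * search_x)
  P[search_z + seq_len(n_z), search_x + seq_len(n_x)] <- B
  us <- seq(-search_x, search_x)
  vs <- seq(-search_z, search_z)
  rho <- matrix(NA_real_, length(vs), length(us))
  rz <- seq_len(n_z)
  cx <- seq_len(n_x)
  for (iv in seq_along(vs)) {
    rows <- rz + vs[iv] + search_z
    for (iu in seq_along(us)) {
      rho[iv, iu] <- sum(A * P[rows, cx + us[iu] + search_x])
    }
  }
  rho <- rho / (s1 * s2)
  peak <- max(rho)
  cand <- which(rho == peak, arr.ind = TRUE)
  u_c <- us[cand[, 2]]
  v_c <- vs[cand[, 1]]
  ord <- order(abs(u_c), abs(v_c), u_c, v_c)
  best <- ord[1]
  list(xshift = u_c[best], zshift = v_c[best], rho = peak)
}
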