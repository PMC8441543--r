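#' Partition the sample region into a grid of ROIs
#'
#' Divides the region strictly between the plates into `N` rows by `M`
#' columns of rectangular ROIs. ROI height follows the plate-separation rule
#' (12 native axial pixels when the measured separation exceeds 200 um, 18
#' when below, giving 15-18 um axial resolution for shear analysis); ROI
#' width is 100 native lateral pixels (~150 um, wide enough to capture a few
#' tracers), scaled by the recorded upsampling factor. A safety margin of
#' half an ROI height is kept from each plate line, and partial ROIs at the
#' edges are discarded.
#'
#' @param flat A `flattened_stack` from [flatten_tilt()].
#' @return An object of class `roi_grid`: fields `n_row`, `n_col`,
#'   `roi_height`, `roi_width` (current pixels), `row_start`, `col_start`
#'   (top-left pixel of each ROI row/column), `depth_um` (physical depth of
#'   each ROI row center below the top plate), `upsample`.
#' @export
partition_grid <- function(flat) {
  stopifnot(inherits(flat, "flattened_stack"))
  roi_h <- roi_height_px(flat$measured_H)
  roi_w <- 100L * flat$upsample
  margin <- ceiling(roi_h / 2)
  first <- flat$top_plate_row + margin
  last <- flat$bottom_plate_row - margin
  n_row <- (last - first + 1) %/% roi_h
  if (n_row < 2) {
    rlang::abort("Sample region holds fewer than 2 complete ROI rows.",
                 class = "octflow_error_invalid_stack")
  }
  n_col <- dim(flat$frames)[2] %/% roi_w
  if (n_col < 1) {
    rlang::abort("Image narrower than one ROI.",
                 class = "octflow_error_invalid_stack")
  }
  row_start <- first + (seq_len(n_row) - 1L) * roi_h
  col_start <- 1L + (seq_len(n_col) - 1L) * roi_w
  centers <- row_start + (roi_h - 1) / 2
  depth_um <- (centers - flat$top_plate_row) * flat$pixel_size_z *
    flat$axial_factor
  structure(
    list(n_row = as.integer(n_row), n_col = as.integer(n_col),
         roi_height = as.integer(roi_h), roi_width = as.integer(roi_w),
         row_start = as.integer(row_start), col_start = as.integer(col_start),
         depth_um = depth_um, upsample = flat$upsample),
    class = "roi_grid")
}

# Extract ROI (i, j) of frame k as a matrix.
roi_pixels <- function(flat, grid, i, j, k) {
  rs <- grid$row_start[i]
  cs <- grid$col_start[j]
  flat$frames[rs:(rs + grid$roi_height - 1L),
              cs:(cs + grid$roi_width - 1L), k]
}

#' Per-row intensity thresholds
#'
#' One threshold per ROI row `i`: the mean pixel intensity of all that row's
#' ROIs pooled over columns `j` and frames `k`, plus `k_sigma` standard
#' deviations. A per-row threshold compensates the depth sensitivity
#' roll-off. Pixels at or below the threshold are zeroed by
#' [apply_threshold()]; pixels above keep their original intensity.
#'
#' @param flat A `flattened_stack`.
#' @param grid An [partition_grid()] result.
#' @param k_sigma Multiplier on the standard deviation (default 1.5).
#' @return Numeric vector of length `grid$n_row`.
#' @export
threshold_rows <- function(flat, grid, k_sigma = 1.5) {
  vapply(seq_len(grid$n_row), function(i) {
    rs <- grid$row_start[i]
    cs_all <- grid$col_start[1]
    ce_all <- grid$col_start[grid$n_col] + grid$roi_width - 1L
    px <- flat$frames[rs:(rs + grid$roi_height - 1L), cs_all:ce_all, ]
    mean(px) + k_sigma * stats::sd(px)
  }, numeric(1))
}

#' Apply a threshold to an ROI
#'
#' @param roi Numeric matrix.
#' @param threshold Scalar threshold; pixels `<= threshold` become 0.
#' @return The thresholded matrix.
#' @export
apply_threshold <- function(roi, threshold) {
  roi[roi <= threshold] <- 0
  roi
}

#' Cluster check for a thresholded ROI
#'
#' Decides whether a thresholded ROI contains a spatially clustered bright
#' feature (a particle) rather than isolated noise pixels: the ROI must have
#' more than one non-zero pixel, and its product with its own copy displaced
#' by one pixel along the image diagonal must be non-zero (i.e. some bright
#' pixel has a bright diagonal neighbour).
#'
#' @param roi Thresholded ROI matrix.
#' @return `TRUE` if the ROI passes, else `FALSE`.
#' @export
cluster_check <- function(roi) {
  nz <- sum(roi != 0)
  if (nz < 2) return(FALSE)
  n_r <- nrow(roi); n_c <- ncol(roi)
  if (n_r < 2 || n_c < 2) return(FALSE)
  diag_sum <- sum(roi[2:n_r, 2:n_c] * roi[1:(n_r - 1), 1:(n_c - 1)])
  diag_sum > 0
}

#' Effective tracer depth of each ROI row
#'
#' The displacement measured in an ROI is that of the tracers it contains,
#' which sit anywhere within the ROI's axial extent (15-18 um), not at its
#' geometric center. For the depth regression, each row is therefore
#' assigned the intensity-weighted centroid depth of its thresholded pixels,
#' pooled over its valid ROIs and a subsample of frames.
#'
#' @param flat A `flattened_stack`.
#' @param grid An [partition_grid()] result.
#' @param thresholds Per-row thresholds from [threshold_rows()].
#' @param validity Validity mask from [build_validity()].
#' @param frame_step Use every `frame_step`-th frame (default 5).
#' @return Numeric vector of per-row depths in micrometers below the top
#'   plate; rows without any above-threshold pixel fall back to the
#'   geometric center depth.
#' @export
effective_depths <- function(flat, grid, thresholds, validity,
                             frame_step = 5L) {
  ks <- seq(1L, n_frames(flat), by = frame_step)
  out <- grid$depth_um
  for (i in seq_len(grid$n_row)) {
    num <- 0; den <- 0
    rows_px <- grid$row_start[i] + seq_len(grid$roi_height) - 1L
    for (j in which(validity[i, ])) {
      for (k in ks) {
        roi <- apply_threshold(roi_pixels(flat, grid, i, j, k),
                               thresholds[i])
        if (any(roi > 0)) {
          w_row <- rowSums(roi)
          num <- num + sum(w_row * rows_px)
          den <- den + sum(w_row)
        }
      }
    }
    if (den > 0) {
      out[i] <- (num / den - flat$top_plate_row) * flat$pixel_size_z *
        flat$axial_factor
    }
  }
  out
}

#' Build the ROI validity mask
#'
#' An ROI `(i, j)` is non-empty only if it passes the cluster check in every
#' frame. Every ROI row must retain at least one non-empty ROI, otherwise the
#' whole stack is invalid for analysis and an error of class
#' `octflow_error_invalid_stack` naming the offending row is raised.
#'
#' @param flat A `flattened_stack`.
#' @param grid An [partition_grid()] result.
#' @param thresholds Per-row thresholds from [threshold_rows()].
#' @return Logical matrix `n_row x n_col`.
#' @export
build_validity <- function(flat, grid, thresholds) {
  Q <- n_frames(flat)
  mask <- matrix(TRUE, grid$n_row, grid$n_col)
  for (i in seq_len(grid$n_row)) {
    for (j in seq_len(grid$n_col)) {
      for (k in seq_len(Q)) {
        roi <- apply_threshold(roi_pixels(flat, grid, i, j, k), thresholds[i])
        if (!cluster_check(roi)) {
          mask[i, j] <- FALSE
          break
        }
      }
    }
    if (!any(mask[i, ])) {
      rlang::abort(
        sprintf("Invalid stack: ROI row %d has no non-empty ROI.", i),
        class = "octflow_error_invalid_stack",
        row = i)
    }
  }
  mask
}
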