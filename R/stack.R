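#' OCT B-mode image stack
#'
#' In-memory container for a time series of B-mode frames. Frames are stored
#' as a numeric array `[z, x, frame]` with intensities in `[0, 1]`, together
#' with acquisition timing and free-space pixel calibration. Column `c` of
#' frame `k` is sampled at `time[k] + (c - 1) / a_line_rate` because A-lines
#' are acquired sequentially within a frame.
#'
#' @param frames Numeric array `[n_z, n_x, n_frames]` (or a list of matrices).
#' @param a_line_rate A-line rate in Hz.
#' @param dead_time Inter-frame dead time in seconds.
#' @param pixel_size_x,pixel_size_z Free-space pixel sizes in micrometers.
#' @param time Optional frame start times (s); reconstructed from the
#'   acquisition timing when `NULL`.
#' @param meta Optional named list of extra metadata (waveform, geometry,
#'   ground truth, processing provenance).
#'
#' @return An object of class `oct_stack`.
#' @export
oct_stack <- function(frames, a_line_rate, dead_time,
                      pixel_size_x, pixel_size_z,
                      time = NULL, meta = list()) {
  if (is.list(frames) && !is.array(frames)) {
    frames <- simplify2array(frames)
  }
  stopifnot(length(dim(frames)) == 3)
  n_x <- dim(frames)[2]
  frame_interval <- n_x / a_line_rate + dead_time
  if (is.null(time)) {
    time <- (seq_len(dim(frames)[3]) - 1) * frame_interval
  }
  structure(
    list(frames = frames,
         time = time,
         a_line_rate = a_line_rate,
         dead_time = dead_time,
         frame_interval = frame_interval,
         pixel_size_x = pixel_size_x,
         pixel_size_z = pixel_size_z,
         upsample = 1L,
         meta = meta),
    class = "oct_stack")
}

#' @export
print.oct_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<oct_stack> %d frames of %d x %d px (z x x)\n", d[3], d[1], d[2]))
  cat(sprintf("  frame interval %.4g ms (A-line rate %.4g kHz, dead time %.3g ms)\n",
              1e3 * x$frame_interval, x$a_line_rate / 1e3, 1e3 * x$dead_time))
  cat(sprintf("  pixel size %.3g x %.3g um (x, z, free space), lateral upsample %dx\n",
              x$pixel_size_x, x$pixel_size_z, x$upsample))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack An [oct_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

# The frame interval implied by acquisition metadata.
frame_interval <- function(stack) stack$frame_interval

#' Write a stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are written as 16-bit grayscale TIFF pages (intensities clipped to
#' `[0, 1]`); acquisition, geometry, waveform and ground-truth metadata go to
#' `<path>.json`. Intensities generated by [generate_stack()] are already
#' quantized to 16-bit levels, so a write/read round trip is exact.
#'
#' @param stack An [oct_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  frames <- pmin(pmax(stack$frames, 0), 1)
  pages <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- list(
    a_line_rate = stack$a_line_rate,
    dead_time = stack$dead_time,
    pixel_size_x = stack$pixel_size_x,
    pixel_size_z = stack$pixel_size_z,
    upsample = stack$upsample,
    time = stack$time,
    meta = serialize_meta(stack$meta))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

serialize_meta <- function(meta) {
  lapply(meta, function(x) {
    if (inherits(x, c("driving_waveform", "chamber_geometry",
                      "fluid_properties"))) {
      c(unclass(x), list(.class = class(x)[1]))
    } else if (tibble::is_tibble(x)) {
      c(as.list(x), list(.class = "tbl_df"))
    } else x
  })
}

deserialize_meta <- function(meta) {
  lapply(meta, function(x) {
    if (is.list(x) && !is.null(x$.class)) {
      cls <- x$.class
      x$.class <- NULL
      x <- lapply(x, function(el) if (is.list(el) && length(el) == 0) NULL else el)
      if (cls == "tbl_df") tibble::as_tibble(x[lengths(x) > 0 | TRUE])
      else structure(x, class = cls)
    } else x
  })
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path with a `<path>.json` sidecar. A missing sidecar or
#'   missing required sidecar fields raise a schema error naming them.
#' @return An [oct_stack()]. Frame start times are reconstructed from the
#'   acquisition timing (`k * (n_x / a_line_rate + dead_time)`) unless the
#'   sidecar carries explicit times.
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    rlang::abort(paste0("Missing JSON sidecar: ", sc),
                 class = "octflow_error_schema")
  }
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  required <- c("a_line_rate", "dead_time", "pixel_size_x", "pixel_size_z")
  missing <- setdiff(required, names(side))
  if (length(missing) > 0) {
    rlang::abort(paste0("Sidecar missing fields: ",
                        paste(missing, collapse = ", ")),
                 class = "octflow_error_schema")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  st <- oct_stack(simplify2array(pages),
                  a_line_rate = side$a_line_rate,
                  dead_time = side$dead_time,
                  pixel_size_x = side$pixel_size_x,
                  pixel_size_z = side$pixel_size_z,
                  time = side$time,
                  meta = deserialize_meta(as.list(side$meta)))
  st$upsample <- if (is.null(side$upsample)) 1L else as.integer(side$upsample)
  st
}
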