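#' Calibrated multi-channel time-lapse stack
#'
#' The universal image container of the package: a 4-dimensional numeric
#' array `[row, col, channel, frame]` of nonnegative intensities together
#' with the spatial calibration (micrometres per pixel) and the frame
#' interval in seconds. All downstream morphometrics are reported in
#' calibrated units.
#'
#' @param data numeric 4-D array `[row, col, channel, frame]`, or a 3-D
#'   array `[row, col, frame]` for a single channel.
#' @param pixel_size_um pixel size in micrometres (> 0).
#' @param frame_interval_s time between consecutive frames in seconds (> 0).
#' @param channels character vector of channel names (e.g. `c("organelle",
#'   "acer")`).
#' @return an object of class `timelapse_stack`.
#' @examples
#' x <- array(runif(16 * 16 * 2 * 3), c(16, 16, 2, 3))
#' ts <- timelapse_stack(x, pixel_size_um = 0.04, frame_interval_s = 5,
#'                       channels = c("organelle", "acer"))
#' ts
#' @export
timelapse_stack <- function(data, pixel_size_um, frame_interval_s,
                            channels = NULL) {
  if (length(dim(data)) == 3L) {
    data <- array(data, c(dim(data)[1:2], 1L, dim(data)[3]))
  }
  if (length(dim(data)) != 4L)
    stopf("`data` must be a [row, col, channel, frame] array")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stopf("`pixel_size_um` must be > 0")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stopf("`frame_interval_s` must be > 0")
  if (dim(data)[4] < 1L) stopf("stack needs at least one frame")
  if (any(data < 0)) stopf("intensities must be nonnegative")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[3]))
  if (length(channels) != dim(data)[3])
    stopf("channel count mismatch: %d names for %d channels",
          length(channels), dim(data)[3])
  dimnames(data) <- list(NULL, NULL, channels, NULL)
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, channels = channels),
    class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<timelapse_stack> %d x %d px, %d channel(s) [%s], %d frame(s)\n",
    d[1], d[2], d[3], paste(x$channels, collapse = ", "), d[4]))
  cat(sprintf("  pixel size %.4g um, frame interval %.4g s (%.4g s total)\n",
              x$pixel_size_um, x$frame_interval_s,
              (d[4] - 1) * x$frame_interval_s))
  invisible(x)
}

#' @export
dim.timelapse_stack <- function(x) dim(x$data)

#' Extract one frame of one channel
#'
#' @param stack a [timelapse_stack].
#' @param frame 1-based frame index.
#' @param channel channel name or index.
#' @return a numeric matrix.
#' @export
get_frame <- function(stack, frame, channel = 1L) {
  stopifnot(inherits(stack, "timelapse_stack"))
  stack$data[, , channel, frame]
}

n_frames <- function(stack) dim(stack$data)[4]

#' Write a time-lapse stack to multi-page TIFF files
#'
#' One 16-bit multi-page TIFF is written per channel
#' (`<basename>_<channel>.tif`), the camera-native format for
#' fluorescence stacks, plus a JSON sidecar (`<basename>.json`) holding
#' the calibration (pixel size, frame interval, channel names, frame
#' count and the intensity scale by which the data were divided before
#' 16-bit quantisation). Writing quantises intensities onto the 65535-step
#' grid; a written file round-trips exactly thereafter. Label-mask stacks
#' from the synthetic generator are written separately by
#' [write_label_stack()].
#'
#' @param stack a [timelapse_stack].
#' @param basename path prefix (without extension).
#' @return `basename`, invisibly.
#' @export
write_timelapse <- function(stack, basename) {
  stopifnot(inherits(stack, "timelapse_stack"))
  scale <- max(stack$data, 1)
  for (ch in stack$channels) {
    pages <- lapply(seq_len(n_frames(stack)),
                    function(f) round(stack$data[, , ch, f] / scale * 65535) / 65535)
    tiff::writeTIFF(pages, paste0(basename, "_", ch, ".tif"),
                    bits.per.sample = 16L, reduce = FALSE)
  }
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_s = stack$frame_interval_s,
               channels = as.list(stack$channels),
               n_frames = n_frames(stack),
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basename)
}

#' Read a time-lapse stack written by [write_timelapse()]
#'
#' Calibration is taken from the JSON sidecar; if the sidecar is absent,
#' `pixel_size_um` and `frame_interval_s` must be supplied explicitly or an
#' error is raised. Intensities are returned exactly as stored (16-bit
#' grid, normalised to at most 1); the original scale is kept in the
#' `intensity_scale` attribute.
#'
#' @param basename path prefix used at write time.
#' @param pixel_size_um,frame_interval_s calibration overrides, required
#'   when no sidecar exists.
#' @param channels channel names to read; defaults to the sidecar list.
#' @return a [timelapse_stack].
#' @export
read_timelapse <- function(basename, pixel_size_um = NULL,
                           frame_interval_s = NULL, channels = NULL) {
  sidecar <- paste0(basename, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(frame_interval_s)) frame_interval_s <- meta$frame_interval_s
  if (is.null(pixel_size_um) || is.null(frame_interval_s))
    stopf("missing calibration: no sidecar at '%s' and no explicit pixel_size_um/frame_interval_s",
          sidecar)
  if (is.null(channels))
    channels <- if (!is.null(meta)) unlist(meta$channels) else "ch1"
  stacks <- lapply(channels, function(ch) {
    f <- paste0(basename, "_", ch, ".tif")
    if (!file.exists(f)) stopf("channel file not found: %s", f)
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages
  })
  nf <- length(stacks[[1]])
  dims <- dim(stacks[[1]][[1]])
  arr <- array(0, c(dims[1], dims[2], length(channels), nf))
  for (i in seq_along(channels))
    for (f in seq_len(nf)) arr[, , i, f] <- stacks[[i]][[f]]
  out <- timelapse_stack(arr, as.numeric(pixel_size_um),
                         as.numeric(frame_interval_s), channels)
  attr(out, "intensity_scale") <-
    if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  out
}

#' Write a label-mask stack as 16-bit multi-page TIFF
#'
#' @param labels integer array `[row, col, frame]` of instance labels
#'   (0 = background, labels up to 65535).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(labels, path) {
  if (max(labels) > 65535L) stopf("labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(labels)[3]), function(f) labels[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read a label-mask stack written by [write_label_stack()]
#'
#' @param path TIFF file.
#' @return integer array `[row, col, frame]`.
#' @export
read_label_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    arr[, , f] <- matrix(as.integer(round(pages[[f]] * 65535)),
                         nrow(pages[[f]]), ncol(pages[[f]]))
  arr
}
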