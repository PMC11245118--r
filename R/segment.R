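#' Configuration for the vesicular-organelle segmentation pipeline
#'
#' Defaults follow the conventions of the classic ImageJ endosome/lysosome
#' macro dialect: rolling-ball style background subtraction (radius 50 px),
#' a 3x3 median "despeckle", a percentile contrast stretch saturating
#' 0.35% of pixels, a final median filter of radius 2 px, a minimum object
#' size of 0.06 um^2 and a maxima prominence of 10% of the frame dynamic
#' range for watershed seeding.
#'
#' @param rolling_ball_radius_px radius of the structuring disc used for
#'   background estimation (grayscale opening).
#' @param despeckle apply the 3x3 median despeckle step.
#' @param saturate_fraction total fraction of pixels saturated by the
#'   linear contrast stretch (split between both tails).
#' @param median_radius_px radius of the final median filter (0 = skip).
#' @param min_area_um2 minimum object area kept by [size_filter()].
#' @param maxima_prominence_frac watershed-seed prominence as a fraction of
#'   the preprocessed frame's dynamic range.
#' @param contrast apply the contrast-stretch step.
#' @return a list of class `vesicle_config`.
#' @export
vesicle_config <- function(rolling_ball_radius_px = 50,
                           despeckle = TRUE,
                           saturate_fraction = 0.0035,
                           median_radius_px = 2,
                           min_area_um2 = 0.06,
                           maxima_prominence_frac = 0.10,
                           contrast = TRUE) {
  structure(as.list(environment()), class = "vesicle_config")
}

#' Preprocess a single vesicle-channel frame
#'
#' Applies, in order: background subtraction (grayscale opening with a
#' disc structuring element of the rolling-ball radius, subtracted from
#' the image), a 3x3 median despeckle, a linear percentile contrast
#' stretch, and a median filter of the configured radius. The output is
#' nonnegative with the same shape as the input.
#'
#' @param image numeric matrix (single channel, single frame).
#' @param config a [vesicle_config()].
#' @return numeric matrix, rescaled to [0, 1] unless the frame is flat
#'   after background removal (then all zeros).
#' @export
preprocess_vesicle_frame <- function(image, config = vesicle_config()) {
  if (min(dim(image)) <= 2 * config$rolling_ball_radius_px)
    stopf("frame (%d x %d) smaller than the rolling-ball diameter (%d px)",
          nrow(image), ncol(image), 2 * config$rolling_ball_radius_px)
  x <- image
  if (config$rolling_ball_radius_px > 0 && max(x) > 0) {
    brush <- EBImage::makeBrush(2 * round(config$rolling_ball_radius_px) + 1,
                                "disc")
    mx <- max(x)  # EBImage grayscale morphology expects intensities in [0, 1]
    bg <- EBImage::dilate(EBImage::erode(x / mx, brush), brush) * mx
    x <- pmax(x - bg, 0)
  }
  if (max(x) == 0) return(x)
  if (config$despeckle) {
    mx <- max(x)
    x <- EBImage::medianFilter(x / mx, 1) * mx
  }
  if (config$contrast) {
    q <- quantile(x, c(config$saturate_fraction / 2,
                       1 - config$saturate_fraction / 2), names = FALSE)
    if (q[2] > q[1]) x <- pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
  }
  if (config$median_radius_px > 0) {
    mx <- max(x)
    if (mx > 0) x <- EBImage::medianFilter(x / mx, config$median_radius_px) * mx
  }
  pmax(x, 0)
}

#' Remove small objects from a binary mask
#'
#' Deletes 8-connected components whose calibrated area falls below
#' `min_area_um2` (default 0.06 um^2, i.e. objects smaller than the
#' conventional noise floor for vesicular organelles at ~40 nm pixels).
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size_um pixel size in micrometres.
#' @param min_area_um2 minimum area kept; components with area strictly
#'   below this are removed.
#' @return logical matrix.
#' @export
size_filter <- function(mask, pixel_size_um, min_area_um2 = 0.06) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask > 0)
  areas <- tabulate(lab[lab > 0L]) * pixel_size_um^2
  keep <- which(areas >= min_area_um2)
  out <- matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
  out
}

#' Find intensity maxima by topographic prominence
#'
#' Detects local maxima whose topographic prominence (peak height above
#' the saddle connecting it to a higher peak, computed by a union-find
#' sweep over pixels in decreasing intensity, 8-connected) reaches
#' `prominence`. This is the classic flood-based maxima detection used for
#' watershed seeding. Ties are broken deterministically in row-major
#' order. If a `mask` is given, the search is restricted to it and
#' prominence is evaluated within each masked component.
#'
#' @param image numeric matrix.
#' @param prominence minimum prominence (intensity units).
#' @param mask optional logical matrix restricting the search.
#' @return integer matrix with one nonzero label per accepted maximum.
#' @export
find_maxima <- function(image, prominence, mask = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  idx <- if (is.null(mask)) seq_len(nr * nc) else which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  vals <- image[idx]
  ord <- idx[order(-vals, idx)]
  in_dom <- logical(nr * nc); in_dom[idx] <- TRUE
  processed <- logical(nr * nc)
  comp <- integer(nr * nc)              # pixel -> component id
  parent <- integer(0)                  # union-find over components
  peak_val <- numeric(0)
  peak_pix <- integer(0)
  alive <- logical(0)
  maxima <- integer(0)
  findp <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  nbr_off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (pix in ord) {
    r <- ((pix - 1L) %% nr) + 1L
    cc <- ((pix - 1L) %/% nr) + 1L
    nb <- pix + nbr_off
    ok <- rep(TRUE, 8L)
    if (r == 1L) ok[c(1L, 5L, 7L)] <- FALSE
    if (r == nr) ok[c(2L, 6L, 8L)] <- FALSE
    if (cc == 1L) ok[c(3L, 5L, 6L)] <- FALSE
    if (cc == nc) ok[c(4L, 7L, 8L)] <- FALSE
    nb <- nb[ok]
    nb <- nb[processed[nb]]
    v <- image[pix]
    if (!length(nb)) {
      k <- length(parent) + 1L
      parent[k] <- k; peak_val[k] <- v; peak_pix[k] <- pix; alive[k] <- TRUE
      comp[pix] <- k
    } else {
      roots <- unique(vapply(comp[nb], findp, integer(1)))
      if (length(roots) == 1L) {
        comp[pix] <- roots
      } else {
        # merge: the component with the highest (earliest) peak survives
        o <- order(-peak_val[roots], peak_pix[roots])
        roots <- roots[o]
        win <- roots[1]
        for (rt in roots[-1]) {
          if (peak_val[rt] - v >= prominence) maxima <- c(maxima, peak_pix[rt])
          parent[rt] <- win
          alive[rt] <- FALSE
        }
        comp[pix] <- win
      }
    }
    processed[pix] <- TRUE
  }
  # surviving components: prominence relative to the lowest value reached
  floor_val <- min(vals)
  for (k in which(alive[seq_along(parent)])) {
    if (findp(k) == k && peak_val[k] - floor_val >= prominence)
      maxima <- c(maxima, peak_pix[k])
  }
  out <- matrix(0L, nr, nc)
  if (length(maxima)) {
    maxima <- sort(maxima)
    out[maxima] <- seq_along(maxima)
  }
  out
}

#' Split touching objects by marker-controlled watershed
#'
#' Seeds are the prominence-filtered maxima of the original (pre-threshold)
#' intensity image restricted to the mask; the mask is then partitioned by
#' marker-controlled watershed (seeded region growing on the intensity
#' manifold). Components containing no seed are kept whole.
#'
#' @param mask binary mask of the thresholded objects.
#' @param original_image the intensity image the mask was derived from.
#' @param maxima_prominence seed prominence; default 10% of the masked
#'   dynamic range.
#' @return integer label matrix, labels contiguous from 1 in row-major
#'   order of first occurrence.
#' @export
split_touching <- function(mask, original_image, maxima_prominence = NULL) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (is.null(maxima_prominence))
    maxima_prominence <- 0.10 * diff(range(original_image[mask]))
  seeds <- find_maxima(original_image, maxima_prominence, mask = mask)
  comps <- label_components(mask)
  if (max(seeds) == 0L) return(relabel_sequential(comps))
  ws <- EBImage::propagate(original_image, seeds, mask = mask)
  ws <- matrix(as.integer(round(as.numeric(ws))), nrow(mask), ncol(mask))
  # components without any seed fall back to their connected component
  seeded <- unique(comps[seeds > 0L])
  unlab <- mask & ws == 0L
  if (any(unlab)) {
    off <- max(ws)
    ws[unlab] <- comps[unlab] + off
  }
  relabel_sequential(ws)
}

#' Per-object morphometrics of a label image
#'
#' For every label: calibrated area, Crofton (4-direction) perimeter,
#' circularity `4*pi*A/P^2` (reported both raw and clamped to [0, 1], the
#' usual convention for digitised shapes) and the intensity-unweighted
#' centroid in micrometres (origin at the top-left corner, y running
#' down).
#'
#' @param labels integer label matrix.
#' @param pixel_size_um pixel size.
#' @param frame optional frame index stored in the output.
#' @return data frame with one row per label: `frame`, `label`,
#'   `area_um2`, `perimeter_um`, `circularity`, `circularity_raw`,
#'   `centroid_x_um`, `centroid_y_um`.
#' @export
analyze_regions <- function(labels, pixel_size_um, frame = NA_integer_) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    return(data.frame(frame = integer(0), label = integer(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0), circularity_raw = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0)))
  nr <- nrow(labels)
  out <- lapply(ids, function(id) {
    pix <- which(labels == id)
    rows <- ((pix - 1L) %% nr) + 1L
    cols <- ((pix - 1L) %/% nr) + 1L
    rb <- range(rows); cb <- range(cols)
    sub <- matrix(FALSE, rb[2] - rb[1] + 1L, cb[2] - cb[1] + 1L)
    sub[cbind(rows - rb[1] + 1L, cols - cb[1] + 1L)] <- TRUE
    per_px <- crofton_perimeter_px(sub)
    area <- length(pix) * pixel_size_um^2
    per <- per_px * pixel_size_um
    circ_raw <- if (per > 0) 4 * pi * area / per^2 else NA_real_
    data.frame(frame = frame, label = id, area_um2 = area,
               perimeter_um = per,
               circularity = min(max(circ_raw, 0), 1),
               circularity_raw = circ_raw,
               centroid_x_um = px_to_um(mean(cols), pixel_size_um),
               centroid_y_um = px_to_um(mean(rows), pixel_size_um))
  })
  do.call(rbind, out)
}

#' Segment one vesicle-channel frame end to end
#'
#' Convenience wrapper chaining [preprocess_vesicle_frame()],
#' [moments_threshold()], [size_filter()] and [split_touching()].
#'
#' @param image raw single-channel frame.
#' @param pixel_size_um pixel size.
#' @param config a [vesicle_config()].
#' @return integer label matrix.
#' @export
segment_vesicles <- function(image, pixel_size_um, config = vesicle_config()) {
  pre <- preprocess_vesicle_frame(image, config)
  if (max(pre) == 0) return(matrix(0L, nrow(image), ncol(image)))
  thr <- moments_threshold(pre)
  mask <- size_filter(pre > thr, pixel_size_um, config$min_area_um2)
  if (!any(mask)) return(matrix(0L, nrow(image), ncol(image)))
  split_touching(mask, pre,
                 maxima_prominence = config$maxima_prominence_frac *
                   diff(range(pre[mask])))
}

#' Segment every frame of a channel
#'
#' @param stack a [timelapse_stack].
#' @param channel channel name or index.
#' @param config a [vesicle_config()].
#' @return integer array `[row, col, frame]` of per-frame labels.
#' @export
segment_stack <- function(stack, channel = "organelle",
                          config = vesicle_config()) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  out <- array(0L, c(d[1], d[2], d[4]))
  for (f in seq_len(d[4]))
    out[, , f] <- segment_vesicles(stack$data[, , channel, f],
                                   stack$pixel_size_um, config)
  out
}

#' Configuration for mitochondrial segmentation
#'
#' @param block_radius_px half-width of the adaptive local-mean window.
#' @param offset threshold offset above the local mean.
#' @param min_area_um2 minimum particle area.
#' @param contrast apply the contrast-stretch preprocessing step (off by
#'   default: adaptive thresholding is already contrast-invariant).
#' @param rolling_ball_radius_px background-subtraction radius.
#' @return a list of class `mito_config`.
#' @export
mito_config <- function(block_radius_px = 16,
                        offset = 0.05,
                        min_area_um2 = 0.06,
                        contrast = FALSE,
                        rolling_ball_radius_px = 50) {
  structure(as.list(environment()), class = "mito_config")
}

#' Segment mitochondria in a single frame
#'
#' Preprocessing as for vesicles (contrast step optional), followed by an
#' adaptive local-mean threshold, particle size filtering and 8-connected
#' labelling - the standard recipe for thresholding thin, branched
#' mitochondrial networks whose intensity varies across the cell.
#'
#' @param image raw single-channel frame.
#' @param pixel_size_um pixel size.
#' @param config a [mito_config()].
#' @return integer label matrix.
#' @export
mito_segment <- function(image, pixel_size_um, config = mito_config()) {
  vc <- vesicle_config(rolling_ball_radius_px = config$rolling_ball_radius_px,
                       contrast = config$contrast)
  pre <- preprocess_vesicle_frame(image, vc)
  if (max(pre) == 0) return(matrix(0L, nrow(image), ncol(image)))
  w <- config$block_radius_px
  mask <- EBImage::thresh(pre / max(pre), w = w, h = w,
                          offset = config$offset) > 0
  mask <- size_filter(mask, pixel_size_um, config$min_area_um2)
  relabel_sequential(label_components(mask))
}
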