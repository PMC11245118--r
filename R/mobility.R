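#' Extract per-frame centroids from a label stack
#'
#' @param labels integer array `[row, col, frame]`.
#' @param pixel_size_um pixel size.
#' @return data frame `frame`, `label`, `x_um`, `y_um`, `area_px`.
#' @export
label_centroids <- function(labels, pixel_size_um) {
  nr <- dim(labels)[1]
  out <- lapply(seq_len(dim(labels)[3]), function(f) {
    m <- labels[, , f]
    pix <- which(m > 0L)
    if (!length(pix)) return(NULL)
    lab <- m[pix]
    ids <- sort(unique(lab))
    rows <- ((pix - 1L) %% nr) + 1L
    cols <- ((pix - 1L) %/% nr) + 1L
    data.frame(frame = f, label = ids,
               x_um = px_to_um(as.numeric(tapply(cols, lab, mean)[as.character(ids)]), pixel_size_um),
               y_um = px_to_um(as.numeric(tapply(rows, lab, mean)[as.character(ids)]), pixel_size_um),
               area_px = as.integer(tapply(rep(1L, length(lab)), lab, sum)[as.character(ids)]))
  })
  do.call(rbind, out)
}

#' Link per-frame detections into tracks
#'
#' Deterministic greedy globally-nearest-pair linking: at each frame
#' transition, candidate (track, detection) pairs within the distance gate
#' are linked in increasing order of distance (ties broken by track then
#' label id); unmatched detections start new tracks. Optional gap closing
#' keeps a track alive for `max_gap_frames` missed frames.
#'
#' @param detections data frame with `frame`, `label`, `x_um`, `y_um`
#'   (e.g. from [label_centroids()]).
#' @param frame_interval_s frame interval.
#' @param max_link_um distance gate per frame transition (default 1 um).
#' @param max_gap_frames number of consecutive missed frames tolerated.
#' @return data frame of class `organelle_tracks`: `track`, `frame`,
#'   `x_um`, `y_um`, with `frame_interval_s` as an attribute.
#' @export
track_organelles <- function(detections, frame_interval_s,
                             max_link_um = 1, max_gap_frames = 0) {
  if (max_link_um < 0) stopf("max_link_um must be >= 0")
  det <- detections[order(detections$frame, detections$label), , drop = FALSE]
  det$track <- NA_integer_
  last_pos <- NULL  # data.frame(track, frame, x, y)
  next_track <- 1L
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    if (!is.null(last_pos))
      last_pos <- last_pos[last_pos$frame >= f - 1L - max_gap_frames, , drop = FALSE]
    if (!is.null(last_pos) && nrow(last_pos) && length(rows)) {
      dx <- outer(last_pos$x, det$x_um[rows], "-")
      dy <- outer(last_pos$y, det$y_um[rows], "-")
      dd <- sqrt(dx^2 + dy^2)
      cand <- which(dd <= max_link_um, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dd[cand], last_pos$track[cand[, 1]],
                     det$label[rows][cand[, 2]])
        used_t <- logical(nrow(last_pos)); used_d <- logical(length(rows))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_t[i] || used_d[j]) next
          used_t[i] <- TRUE; used_d[j] <- TRUE
          det$track[rows[j]] <- last_pos$track[i]
        }
      }
    }
    new <- rows[is.na(det$track[rows])]
    if (length(new)) {
      det$track[new] <- next_track + seq_along(new) - 1L
      next_track <- next_track + length(new)
    }
    upd <- data.frame(track = det$track[rows], frame = f,
                      x = det$x_um[rows], y = det$y_um[rows])
    if (is.null(last_pos)) last_pos <- upd
    else {
      last_pos <- last_pos[!(last_pos$track %in% upd$track), , drop = FALSE]
      last_pos <- rbind(last_pos, upd)
    }
  }
  out <- det[, c("track", "frame", "x_um", "y_um")]
  out <- out[order(out$track, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- c("organelle_tracks", "data.frame")
  out
}

#' Per-track summary metrics
#'
#' @param tracks an `organelle_tracks` data frame.
#' @param frame_interval_s frame interval; defaults to the attribute set
#'   by [track_organelles()].
#' @return data frame: `track`, `n_points`, `duration_s`,
#'   `displacement_um` (Euclidean start to end), `path_length_um`,
#'   `velocity_um_s` (mean straight velocity).
#' @export
track_stats <- function(tracks, frame_interval_s = attr(tracks, "frame_interval_s")) {
  if (is.null(frame_interval_s)) stopf("frame_interval_s required")
  if (!nrow(tracks))
    return(data.frame(track = integer(0), n_points = integer(0),
                      duration_s = numeric(0), displacement_um = numeric(0),
                      path_length_um = numeric(0), velocity_um_s = numeric(0)))
  sp <- split(tracks, tracks$track)
  out <- lapply(sp, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    dur <- (tr$frame[n] - tr$frame[1]) * frame_interval_s
    disp <- sqrt((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2)
    path <- if (n > 1) sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)) else 0
    data.frame(track = tr$track[1], n_points = n, duration_s = dur,
               displacement_um = disp, path_length_um = path,
               velocity_um_s = if (dur > 0) disp / dur else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Drop short tracks
#'
#' Tracks shorter than `min_duration_s` (default 10 s) are treated as
#' detection noise and removed.
#'
#' @param tracks an `organelle_tracks` data frame.
#' @param min_duration_s minimum duration kept (strictly shorter tracks
#'   are dropped).
#' @param frame_interval_s frame interval; defaults to the attribute.
#' @return filtered `organelle_tracks`.
#' @export
filter_tracks <- function(tracks, min_duration_s = 10,
                          frame_interval_s = attr(tracks, "frame_interval_s")) {
  st <- track_stats(tracks, frame_interval_s)
  keep <- st$track[st$duration_s >= min_duration_s]
  out <- tracks[tracks$track %in% keep, , drop = FALSE]
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- class(tracks)
  out
}

#' Mean straight velocity of a single track
#'
#' Euclidean start-to-end displacement divided by track duration; a closed
#' loop therefore has velocity 0 regardless of path length.
#'
#' @param track data frame with `frame`, `x_um`, `y_um` for one track.
#' @param frame_interval_s frame interval.
#' @return velocity in um/s.
#' @export
mean_straight_velocity <- function(track, frame_interval_s = attr(track, "frame_interval_s")) {
  if (nrow(track) < 2) stopf("track has fewer than two points")
  if (is.null(frame_interval_s)) stopf("frame_interval_s required")
  tr <- track[order(track$frame), , drop = FALSE]
  n <- nrow(tr)
  dur <- (tr$frame[n] - tr$frame[1]) * frame_interval_s
  sqrt((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2) / dur
}

#' Thresholded Manders colocalization coefficients
#'
#' `M1` is the fraction of image A's above-threshold intensity lying where
#' B is also above its threshold; `M2` is the symmetric quantity for B.
#' Both lie in [0, 1].
#'
#' @param image_a,image_b numeric matrices of identical geometry.
#' @param threshold_a,threshold_b channel thresholds (>= 0); pixels
#'   strictly above threshold count as signal.
#' @return named numeric vector `c(M1, M2)`.
#' @export
manders_coefficients <- function(image_a, image_b, threshold_a, threshold_b) {
  if (!identical(dim(image_a), dim(image_b)))
    stopf("images must share geometry")
  if (threshold_a < 0 || threshold_b < 0) stopf("thresholds must be >= 0")
  sel_a <- image_a > threshold_a
  sel_b <- image_b > threshold_b
  den_a <- sum(image_a[sel_a]); den_b <- sum(image_b[sel_b])
  if (den_a == 0 || den_b == 0) stopf("no signal above threshold")
  c(M1 = sum(image_a[sel_a & sel_b]) / den_a,
    M2 = sum(image_b[sel_a & sel_b]) / den_b)
}

#' First-frame autocorrelation curve of a channel
#'
#' Computes, for every offset t >= 1, the thresholded Manders coefficients
#' between frame 1 and frame 1 + t of the same channel, using per-frame
#' automatic (IsoData) or fixed thresholds. Because organelle movement
#' decorrelates the above-threshold supports, the curve's decay rate is a
#' segmentation-free proxy for organelle mobility; its value at offset 0
#' is 1 by definition. The curve value is the mean of M1 and M2 (both
#' components are retained).
#'
#' @param stack a [timelapse_stack] (or a 3-D array of frames).
#' @param channel channel name or index.
#' @param threshold `"isodata"` for per-frame automatic thresholds, or a
#'   numeric fixed threshold applied to every frame.
#' @param value one of `"mean"`, `"M1"`, `"M2"`: which component the
#'   `value` column reports.
#' @param frame_interval_s frame interval (taken from the stack when
#'   available).
#' @return data frame of class `correlation_curve`: `offset_s`, `m1`,
#'   `m2`, `value`, starting with the offset-0 row at value 1.
#' @export
autocorrelation_curve <- function(stack, channel = "organelle",
                                  threshold = "isodata",
                                  value = c("mean", "M1", "M2"),
                                  frame_interval_s = NULL) {
  value <- match.arg(value)
  if (inherits(stack, "timelapse_stack")) {
    frames <- stack$data[, , channel, ]
    if (is.null(frame_interval_s)) frame_interval_s <- stack$frame_interval_s
  } else frames <- stack
  if (is.null(frame_interval_s)) stopf("frame_interval_s required")
  nfr <- dim(frames)[3]
  if (nfr < 2) stopf("need at least two frames")
  f1 <- frames[, , 1]
  if (max(f1) <= 0) stopf("empty first frame")
  thr <- function(img) {
    if (identical(threshold, "isodata")) isodata_threshold(img) else threshold
  }
  t1 <- thr(f1)
  rows <- lapply(seq_len(nfr - 1L), function(t) {
    ft <- frames[, , t + 1L]
    mm <- manders_coefficients(f1, ft, t1, thr(ft))
    data.frame(offset_s = t * frame_interval_s, m1 = mm[["M1"]], m2 = mm[["M2"]])
  })
  out <- do.call(rbind, rows)
  out <- rbind(data.frame(offset_s = 0, m1 = 1, m2 = 1), out)
  out$value <- switch(value, mean = (out$m1 + out$m2) / 2,
                      M1 = out$m1, M2 = out$m2)
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Condition-level mobility summaries
#'
#' Velocities are aggregated per cell then per condition (mean across cell
#' means, spread as SD across cells, via [aggregate_per_cell()]); a set of
#' per-cell autocorrelation curves is reduced to per-timepoint condition
#' mean and SEM across cells, the input expected by
#' [modified_chi_squared()].
#'
#' @param velocities optional data frame with columns `velocity_um_s`,
#'   `cell`, `condition`.
#' @param curves optional named list: `curves[[condition]][[cell]]` is a
#'   `correlation_curve`.
#' @return list with `velocity` (see [aggregate_per_cell()]) and `curves`
#'   (data frame: condition, offset_s, mean, sem, n_cells).
#' @export
summarize_mobility <- function(velocities = NULL, curves = NULL) {
  out <- list()
  if (!is.null(velocities))
    out$velocity <- aggregate_per_cell(velocities, "velocity_um_s")
  if (!is.null(curves)) {
    rows <- lapply(names(curves), function(cond) {
      cc <- curves[[cond]]
      offs <- cc[[1]]$offset_s
      vals <- vapply(cc, function(cv) cv$value, numeric(length(offs)))
      vals <- matrix(vals, nrow = length(offs))
      n <- ncol(vals)
      data.frame(condition = cond, offset_s = offs,
                 mean = rowMeans(vals),
                 sem = apply(vals, 1, sd) / sqrt(n),
                 n_cells = n)
    })
    out$curves <- do.call(rbind, rows)
  }
  out
}
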