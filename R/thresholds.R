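# Automatic grey-level thresholds. Both operate on the 256-bin histogram of
# the min-max rescaled image, so the resulting binary partition is invariant
# under positive affine rescaling of the intensities. Foreground is defined
# as `image > threshold`.

hist256 <- function(image) {
  r <- range(image)
  if (!is.finite(r[1]) || !is.finite(r[2]))
    stopf("image contains non-finite values")
  if (r[1] == r[2]) stopf("degenerate histogram: image is constant")
  xr <- (image - r[1]) / (r[2] - r[1])
  counts <- tabulate(pmin(255L, as.integer(xr * 256)) + 1L, 256L)
  list(counts = counts, range = r)
}

bin_to_intensity <- function(bin01, r) bin01 * (r[2] - r[1]) + r[1]

#' Moment-preserving (Tsai) threshold
#'
#' Computes the threshold of Tsai's moment-preserving method (the "Moments"
#' auto-threshold of common image-analysis software) on the 256-bin
#' histogram of the min-max rescaled image: the image is modelled as a
#' two-level picture whose first three grey-level moments equal those of
#' the input, and the threshold is the histogram quantile at the resulting
#' background fraction.
#'
#' @param image numeric matrix with at least two distinct values.
#' @return threshold on the original intensity scale; foreground pixels are
#'   those with `image > threshold`.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' moments_threshold(img)
#' @export
moments_threshold <- function(image) {
  h <- hist256(image)
  p <- h$counts / sum(h$counts)
  v <- (0:255) / 255
  m1 <- sum(p * v); m2 <- sum(p * v^2); m3 <- sum(p * v^3)
  cd <- m2 - m1^2
  if (cd <= 0) stopf("degenerate histogram: zero variance")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- 0.5 * (-c1 - disc)
  z1 <- 0.5 * (-c1 + disc)
  p0 <- (z1 - m1) / (z1 - z0)          # fraction of pixels below threshold
  cs <- cumsum(p)
  t_idx <- which.min(abs(cs - p0))
  # cut midway between the selected bin and the next, so the threshold lies
  # strictly between the two classes of a well-separated histogram
  bin_to_intensity((v[t_idx] + v[min(t_idx + 1L, 256L)]) / 2, h$range)
}

#' IsoData (iterative intermeans) threshold
#'
#' The classic Ridler-Calvard / IsoData rule (the default auto-threshold of
#' common image-analysis software): iterate `t <- (mean(below t) +
#' mean(above t)) / 2` on the 256-bin histogram until it stabilises.
#'
#' @inheritParams moments_threshold
#' @return threshold on the original intensity scale (a fixed point of the
#'   intermeans iteration); foreground is `image > threshold`.
#' @export
isodata_threshold <- function(image) {
  h <- hist256(image)
  p <- h$counts / sum(h$counts)
  v <- (0:255) / 255
  t <- 0.5
  for (iter in 1:256) {
    below <- v <= t
    w0 <- sum(p[below]); w1 <- sum(p[!below])
    if (w0 == 0 || w1 == 0) {
      # push towards the populated side and continue
      t <- if (w0 == 0) min(v[p > 0]) else max(v[p > 0])
      next
    }
    mu0 <- sum(p[below] * v[below]) / w0
    mu1 <- sum(p[!below] * v[!below]) / w1
    tn <- (mu0 + mu1) / 2
    if (abs(tn - t) < 1e-9) { t <- tn; break }
    t <- tn
  }
  bin_to_intensity(t, h$range)
}

#' Top-fraction intensity mask
#'
#' Masks the pixels whose intensity lies in the top `fraction` of the
#' frame's dynamic range: `image >= (1 - fraction) * max(image)`. With the
#' default `fraction = 0.25` this reproduces the "top 25% of signal based
#' on maximum pixel intensity" convention used to isolate ER-actin
#' hotspots from the diffuse ER background. The maximum is taken per
#' frame. An all-zero frame yields an empty mask.
#'
#' @param image numeric matrix (single frame).
#' @param fraction fraction of the intensity range to keep, in (0, 1].
#' @return logical matrix.
#' @export
top_fraction_mask <- function(image, fraction = 0.25) {
  if (!(fraction > 0 && fraction <= 1)) stopf("`fraction` must be in (0, 1]")
  mx <- max(image)
  if (mx <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  image >= (1 - fraction) * mx
}

#' Top-fraction masks for every frame of a channel
#'
#' @param stack a [timelapse_stack].
#' @param channel channel name or index.
#' @param fraction see [top_fraction_mask()].
#' @return logical array `[row, col, frame]`.
#' @export
top_fraction_mask_stack <- function(stack, channel = "acer", fraction = 0.25) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$data)
  out <- array(FALSE, c(d[1], d[2], d[4]))
  for (f in seq_len(d[4]))
    out[, , f] <- top_fraction_mask(stack$data[, , channel, f], fraction)
  out
}
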