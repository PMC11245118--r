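# In-code fixtures and independent oracles shared across the suite.

disc_image <- function(nr, nc, cx, cy, radius, value = 1, base = 0) {
  m <- matrix(base, nr, nc)
  orgadyn:::draw_disc(m, cx, cy, radius, value)
}

# deterministic pseudo-random 2-level image for threshold tests
bimodal_image <- function(seed, n0 = 1500, n1 = 1500, mu = c(40, 150),
                          sd = c(10, 25)) {
  set.seed(seed)
  matrix(c(rnorm(n0, mu[1], sd[1]), rnorm(n1, mu[2], sd[2])),
         nrow = 50)
}

# --- independent threshold oracles (exhaustive search over 256 cut points) --

# Tsai criterion: for each cut, set two levels preserving the first two
# moments at that background fraction and score the third-moment error.
oracle_moments_threshold <- function(img) {
  r <- range(img)
  xr <- (img - r[1]) / (r[2] - r[1])
  h <- tabulate(pmin(255L, as.integer(xr * 256)) + 1L, 256L)
  p <- h / sum(h)
  v <- (0:255) / 255
  m1 <- sum(p * v); m2 <- sum(p * v^2); m3 <- sum(p * v^3)
  cd <- m2 - m1^2
  best <- NA_integer_; berr <- Inf
  for (t in 1:255) {
    q <- sum(p[1:t])
    if (q <= 0 || q >= 1) next
    z0 <- m1 - sqrt((1 - q) / q * cd)
    z1 <- m1 + sqrt(q / (1 - q) * cd)
    err <- abs(q * z0^3 + (1 - q) * z1^3 - m3)
    if (err < berr) { berr <- err; best <- t }
  }
  (v[best] + v[min(best + 1L, 256L)]) / 2 * (r[2] - r[1]) + r[1]
}

# IsoData criterion: cut whose value is closest to the mean of its two
# class means.
oracle_isodata_threshold <- function(img) {
  r <- range(img)
  xr <- (img - r[1]) / (r[2] - r[1])
  h <- tabulate(pmin(255L, as.integer(xr * 256)) + 1L, 256L)
  p <- h / sum(h)
  v <- (0:255) / 255
  best <- NA_integer_; berr <- Inf
  for (t in 1:255) {
    below <- v <= v[t]
    w0 <- sum(p[below]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mm <- (sum(p[below] * v[below]) / w0 + sum(p[!below] * v[!below]) / w1) / 2
    err <- abs(v[t] - mm)
    if (err < berr) { berr <- err; best <- t }
  }
  v[best] * (r[2] - r[1]) + r[1]
}

# Fisher oracle: enumerate every 2x2 table with the observed margins and
# sum the probabilities (by exact products of choose()) of those no more
# probable than the observed table.
oracle_fisher_exact <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  prob <- vapply(support, function(a) {
    choose(rs[1], a) * choose(rs[2], cs[1] - a) / choose(n, cs[1])
  }, numeric(1))
  obs <- choose(rs[1], tab[1, 1]) * choose(rs[2], cs[1] - tab[1, 1]) /
    choose(n, cs[1])
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# hand-built label stack: one disc object that splits at `split_frame`
# (last parent frame) into two daughters; optionally re-merges
# `merge_after` frames later (kiss-and-run).
toy_split_stack <- function(n_frames, split_frame, merge_after = NA,
                            nr = 40, nc = 40) {
  labs <- array(0L, c(nr, nc, n_frames))
  for (f in seq_len(n_frames)) {
    m <- matrix(0, nr, nc)
    if (f <= split_frame ||
        (!is.na(merge_after) && f >= split_frame + merge_after)) {
      id <- if (f <= split_frame) 1 else 4
      m <- orgadyn:::draw_disc(m, 20, 20, 8, id)
    } else {
      m <- orgadyn:::draw_disc(m, 14, 20, 6, 2)
      m <- orgadyn:::draw_disc(m, 27, 20, 6, 3)
    }
    labs[, , f] <- m
  }
  labs
}
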