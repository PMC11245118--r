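# Low-level helpers shared across modules. Image matrices are indexed
# [row, col] with the origin at the top-left corner and rows running down.
# The centre of pixel (r, c) (1-based) sits at ((c - 0.5), (r - 0.5)) pixels,
# i.e. x_um = (c - 0.5) * pixel_size_um, y_um = (r - 0.5) * pixel_size_um.

px_to_um <- function(idx, pixel_size_um) (idx - 0.5) * pixel_size_um
um_to_px <- function(um, pixel_size_um) um / pixel_size_um + 0.5

#' Evaluate code with a temporary RNG seed
#'
#' Sets the global seed, runs `code`, and restores the previous RNG state so
#' callers never perturb the session stream. All stochastic operations in the
#' package funnel through this helper.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc), padding with `fill`.
mat_shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-connected labelling. EBImage::bwlabel() is 4-connected; a second pass
# unions labels that touch diagonally.
label_components <- function(mask) {
  mask <- mask > 0
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(as.numeric(lab))), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k < 2L) return(lab)
  pairs <- NULL
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nrow(lab) - 1L), , drop = FALSE]
    b <- lab[-1L, , drop = FALSE]
    if (d[2] == 1L) {
      a <- a[, seq_len(ncol(lab) - 1L), drop = FALSE]
      b <- b[, -1L, drop = FALSE]
    } else {
      a <- a[, -1L, drop = FALSE]
      b <- b[, seq_len(ncol(lab) - 1L), drop = FALSE]
    }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(k)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- findp(pairs[i, 1]); rb <- findp(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), findp, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# Relabel a label matrix so labels are contiguous 1..K in row-major order of
# first occurrence (deterministic).
relabel_sequential <- function(lab) {
  v <- as.integer(lab)
  pos <- v > 0L
  u <- unique(v[pos])
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- v
  out[pos] <- match(v[pos], u)
  matrix(out, nrow(lab), ncol(lab))
}

# Crofton 4-direction perimeter estimate (pixel units). Counts foreground /
# background transitions along rows, columns and the two diagonals:
#   P = (pi / 8) * (N0 + N90 + (N45 + N135) / sqrt(2))
# For a digital disc of radius 50 px this is within ~1% of 2*pi*r.
crofton_perimeter_px <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  n0 <- sum(pad[, -1L] != pad[, -ncol(pad)])
  n90 <- sum(pad[-1L, ] != pad[-nrow(pad), ])
  n45 <- sum(pad[-1L, -1L] != pad[-nrow(pad), -ncol(pad)])
  n135 <- sum(pad[-1L, -ncol(pad)] != pad[-nrow(pad), -1L])
  (pi / 8) * (n0 + n90 + (n45 + n135) / sqrt(2))
}

# Rasterise a filled disc into an existing matrix, returning modified copy.
# cx, cy in pixel coordinates (continuous, origin top-left), radius in px.
draw_disc <- function(m, cx, cy, radius, value = 1) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(1L, floor(cy - radius)); r1 <- min(nr, ceiling(cy + radius) + 1L)
  c0 <- max(1L, floor(cx - radius)); c1 <- min(nc, ceiling(cx + radius) + 1L)
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  dy <- (rr - 0.5) - cy
  dx <- (cc - 0.5) - cx
  hit <- outer(dy^2, dx^2, "+") <= radius^2
  sub <- m[rr, cc, drop = FALSE]
  sub[hit] <- value
  m[rr, cc] <- sub
  m
}

# Rasterise a filled capsule (segment of half-length hl at angle theta,
# width = 2 * radius) centred at (cx, cy); used for tubule organelles.
draw_capsule <- function(m, cx, cy, theta, hl, radius, value = 1) {
  ux <- cos(theta); uy <- sin(theta)
  ex <- max(abs(ux * hl), 0) + radius; ey <- max(abs(uy * hl), 0) + radius
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(1L, floor(cy - ey)); r1 <- min(nr, ceiling(cy + ey) + 1L)
  c0 <- max(1L, floor(cx - ex)); c1 <- min(nc, ceiling(cx + ex) + 1L)
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  py <- (rr - 0.5) - cy
  px <- (cc - 0.5) - cx
  # projection of each pixel onto the segment axis, clamped to [-hl, hl]
  grid_x <- matrix(px, length(rr), length(cc), byrow = TRUE)
  grid_y <- matrix(py, length(rr), length(cc))
  t <- pmin(pmax(grid_x * ux + grid_y * uy, -hl), hl)
  d2 <- (grid_x - t * ux)^2 + (grid_y - t * uy)^2
  sub <- m[rr, cc, drop = FALSE]
  sub[d2 <= radius^2] <- value
  m[rr, cc] <- sub
  m
}

# md5 of an R object via canonical serialisation (version 2, no compression).
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
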