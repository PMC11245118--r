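#' Topological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels (two sub-iterations per pass) until no
#' pixel can be removed, yielding an 8-connected, one-pixel-wide skeleton
#' that preserves the topology of the input mask.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  img <- (mask > 0) * 1L
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p2 <- mat_shift(img, 1, 0)   # value of the neighbour above, etc.
      p3 <- mat_shift(img, 1, -1)
      p4 <- mat_shift(img, 0, -1)
      p5 <- mat_shift(img, -1, -1)
      p6 <- mat_shift(img, -1, 0)
      p7 <- mat_shift(img, -1, 1)
      p8 <- mat_shift(img, 0, 1)
      p9 <- mat_shift(img, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 0) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- img == 1L & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img > 0L
}

# Skeleton length in pixels: orthogonal steps count 1, diagonal steps
# sqrt(2); a diagonal step is only counted when it is not shortcut by the
# two orthogonal bridge pixels. A single isolated skeleton pixel counts as
# length 1 (documented convention).
skeleton_length_px <- function(skel) {
  s <- (skel > 0) * 1L
  n <- sum(s)
  if (n == 0L) return(0)
  if (n == 1L) return(1)
  n_orth <- sum(s[-1, ] & s[-nrow(s), ]) + sum(s[, -1] & s[, -ncol(s)])
  # diagonals with redundancy suppression
  a <- s[-nrow(s), -ncol(s)]; b <- s[-1, -1]          # \ direction
  br1 <- s[-nrow(s), -1]; br2 <- s[-1, -ncol(s)]
  n_d1 <- sum(a & b & !(br1 | br2))
  a2 <- s[-nrow(s), -1]; b2 <- s[-1, -ncol(s)]        # / direction
  br3 <- s[-nrow(s), -ncol(s)]; br4 <- s[-1, -1]
  n_d2 <- sum(a2 & b2 & !(br3 | br4))
  n_orth + sqrt(2) * (n_d1 + n_d2)
}

# Number of skeleton neighbours of each skeleton pixel (8-connectivity).
skeleton_degree <- function(skel) {
  s <- (skel > 0) * 1L
  deg <- mat_shift(s, 1, 0) + mat_shift(s, -1, 0) + mat_shift(s, 0, 1) +
    mat_shift(s, 0, -1) + mat_shift(s, 1, 1) + mat_shift(s, 1, -1) +
    mat_shift(s, -1, 1) + mat_shift(s, -1, -1)
  deg[!skel] <- 0L
  deg
}

#' Skeleton morphometrics per mitochondrion
#'
#' For each label: the thinning skeleton, its calibrated length (diagonal
#' steps weighted by sqrt(2)), the number of branches (connected segments
#' remaining after removing junction pixels, i.e. skeleton pixels with
#' three or more skeleton neighbours) and branches per micrometre of
#' skeleton. An unbranched object counts one branch; a label whose
#' skeleton collapses to a single pixel has length one pixel and zero
#' branches.
#'
#' @param labels integer label matrix (from [mito_segment()]).
#' @param pixel_size_um pixel size.
#' @param frame optional frame index stored in the output.
#' @return data frame with one row per label: `frame`, `label`,
#'   `area_um2`, `skeleton_length_um`, `branch_count`, `branches_per_um`.
#' @export
mito_skeleton_stats <- function(labels, pixel_size_um, frame = NA_integer_) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    return(data.frame(frame = integer(0), label = integer(0),
                      area_um2 = numeric(0), skeleton_length_um = numeric(0),
                      branch_count = integer(0), branches_per_um = numeric(0)))
  nr <- nrow(labels)
  out <- lapply(ids, function(id) {
    pix <- which(labels == id)
    rows <- ((pix - 1L) %% nr) + 1L
    cols <- ((pix - 1L) %/% nr) + 1L
    rb <- range(rows); cb <- range(cols)
    # pad by one pixel so thinning sees a background border
    sub <- matrix(FALSE, rb[2] - rb[1] + 3L, cb[2] - cb[1] + 3L)
    sub[cbind(rows - rb[1] + 2L, cols - cb[1] + 2L)] <- TRUE
    skel <- skeletonize(sub)
    len_px <- skeleton_length_px(skel)
    nsk <- sum(skel)
    if (nsk <= 1L) {
      branches <- 0L
    } else {
      deg <- skeleton_degree(skel)
      body <- skel & deg < 3L
      branches <- max(label_components(body))
      if (branches == 0L) branches <- 1L  # e.g. a tight junction cluster
    }
    len_um <- len_px * pixel_size_um
    data.frame(frame = frame, label = id,
               area_um2 = length(pix) * pixel_size_um^2,
               skeleton_length_um = len_um,
               branch_count = as.integer(branches),
               branches_per_um = branches / len_um)
  })
  do.call(rbind, out)
}
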