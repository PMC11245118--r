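#' Build a temporal lineage graph from per-frame label masks
#'
#' Labels in frame `t` are connected to labels in frame `t + 1` whenever
#' their pixel overlap reaches `min_overlap_px`. Overlap-based linking is
#' used (rather than centroid distance) because fission daughters overlap
#' the parent footprint by construction. Nodes carry per-label area and
#' centroid; the label stack is retained for event-site localisation.
#'
#' @param labels integer array `[row, col, frame]` of per-frame instance
#'   labels (any positive integers; labels need not be consistent across
#'   frames).
#' @param pixel_size_um pixel size.
#' @param frame_interval_s frame interval in seconds.
#' @param min_overlap_px minimum shared pixel count for a temporal edge.
#' @param min_overlap_frac additionally require the overlap to reach this
#'   fraction of the smaller of the two region areas (0 disables).
#'   Relative gating suppresses grazing overlaps created when a
#'   neighbouring organelle drifts through another's previous footprint,
#'   which would otherwise contaminate the lineage with spurious
#'   branches; 0.25 is the package's standard setting for event
#'   detection.
#' @return an object of class `lineage_graph` with `nodes` (frame, label,
#'   area_px, centroid), `edges` (frame, from, to, overlap_px) and the
#'   calibration.
#' @export
build_lineage <- function(labels, pixel_size_um, frame_interval_s,
                          min_overlap_px = 1, min_overlap_frac = 0) {
  stopifnot(length(dim(labels)) == 3L)
  nfr <- dim(labels)[3]
  nr <- dim(labels)[1]
  nodes <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    m <- labels[, , f]
    ids <- sort(unique(m[m > 0L]))
    if (!length(ids)) { nodes[[f]] <- NULL; next }
    pix <- which(m > 0L)
    lab <- m[pix]
    rows <- ((pix - 1L) %% nr) + 1L
    cols <- ((pix - 1L) %/% nr) + 1L
    nodes[[f]] <- data.frame(
      frame = f, label = ids,
      area_px = as.integer(tapply(rep(1L, length(lab)), lab, sum)[as.character(ids)]),
      cx_px = as.numeric(tapply(cols, lab, mean)[as.character(ids)]),
      cy_px = as.numeric(tapply(rows, lab, mean)[as.character(ids)]))
  }
  edges <- vector("list", max(nfr - 1L, 0L))
  for (f in seq_len(nfr - 1L)) {
    a <- labels[, , f]; b <- labels[, , f + 1L]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    key <- paste(a[sel], b[sel])
    tab <- table(key)
    ft <- strsplit(names(tab), " ", fixed = TRUE)
    ov <- as.integer(tab)
    keep <- ov >= min_overlap_px
    if (!any(keep)) next
    edges[[f]] <- data.frame(
      frame = f,
      from = as.integer(vapply(ft[keep], `[`, "", 1L)),
      to = as.integer(vapply(ft[keep], `[`, "", 2L)),
      overlap_px = ov[keep])
  }
  nodes <- do.call(rbind, nodes)
  edges <- do.call(rbind, edges)
  if (min_overlap_frac > 0 && !is.null(edges) && nrow(edges)) {
    nk <- paste(nodes$frame, nodes$label)
    a_from <- nodes$area_px[match(paste(edges$frame, edges$from), nk)]
    a_to <- nodes$area_px[match(paste(edges$frame + 1L, edges$to), nk)]
    edges <- edges[edges$overlap_px >= min_overlap_frac * pmin(a_from, a_to), ,
                   drop = FALSE]
  }
  structure(list(
    nodes = nodes,
    edges = edges,
    labels = labels,
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s), class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("<lineage_graph> %d frames, %d nodes, %d edges\n",
              dim(x$labels)[3],
              if (is.null(x$nodes)) 0L else nrow(x$nodes),
              if (is.null(x$edges)) 0L else nrow(x$edges)))
  invisible(x)
}

edge_key <- function(frame, label) paste(frame, label)

#' Detect fission events under persistence rules
#'
#' A fission is a lineage node with two or more next-frame daughters whose
#' parent chain has existed as a single, unbranched object for at least
#' `min_pre_s` before the split and whose daughters remain present and
#' mutually separate for at least `min_post_s` after it. Daughter chains
#' that die, merge with anything, or re-merge with each other inside the
#' window ("kiss and run") disqualify the event. The event site is the
#' centroid of the interface between the daughter regions within the
#' parent footprint (the pre-split constriction).
#'
#' Before the rules are evaluated, grazing lineage edges are pruned by a
#' relative-dominance criterion: an edge is kept only when its overlap
#' reaches `edge_dominance` times the strongest in-edge of its target. A
#' genuine split keeps both daughter edges (each daughter's dominant
#' predecessor is the parent) and a genuine merge keeps both parent edges
#' (comparable overlaps), while the incidental one-frame overlap produced
#' when a neighbouring object brushes through another's previous footprint
#' is dominated by the target's own chain edge and disappears.
#'
#' @param lineage a [build_lineage()] result.
#' @param min_pre_s minimum single-object persistence before the split.
#' @param min_post_s minimum daughter separation after the split.
#' @param edge_dominance relative-dominance threshold in (0, 1]; 0
#'   disables pruning.
#' @return a data frame of class `fission_events`: `split_frame` (last
#'   frame of the parent), `parent_label`, `daughter_labels`
#'   (slash-separated), `site_x_um`, `site_y_um`, `pre_duration_s`,
#'   `post_separation_s`.
#' @export
detect_fission_events <- function(lineage, min_pre_s = 30, min_post_s = 30,
                                  edge_dominance = 0.5) {
  stopifnot(inherits(lineage, "lineage_graph"))
  dt <- lineage$frame_interval_s
  if (!is.numeric(dt) || dt <= 0) stopf("frame_interval_s must be > 0")
  e <- lineage$edges
  if (!is.null(e) && nrow(e) && edge_dominance > 0) {
    ik <- edge_key(e$frame + 1L, e$to)
    max_in <- tapply(e$overlap_px, ik, max)[ik]
    e <- e[e$overlap_px >= edge_dominance * max_in, , drop = FALSE]
  }
  empty <- data.frame(split_frame = integer(0), parent_label = integer(0),
                      daughter_labels = character(0), site_x_um = numeric(0),
                      site_y_um = numeric(0), pre_duration_s = numeric(0),
                      post_separation_s = numeric(0))
  class(empty) <- c("fission_events", "data.frame")
  if (is.null(e) || !nrow(e)) return(empty)
  nfr <- dim(lineage$labels)[3]
  out_key <- edge_key(e$frame, e$from)
  in_key <- edge_key(e$frame + 1L, e$to)
  outdeg <- table(out_key)
  indeg <- table(in_key)
  odeg <- function(f, l) { v <- outdeg[edge_key(f, l)]; ifelse(is.na(v), 0L, as.integer(v)) }
  ideg <- function(f, l) { v <- indeg[edge_key(f, l)]; ifelse(is.na(v), 0L, as.integer(v)) }
  succ <- function(f, l) e[e$frame == f & e$from == l, , drop = FALSE]
  pred <- function(f, l) e[e$frame == f - 1L & e$to == l, , drop = FALSE]

  cand <- unique(e[duplicated(out_key) |
                     duplicated(out_key, fromLast = TRUE), c("frame", "from")])
  res <- NULL
  for (k in seq_len(nrow(cand))) {
    f <- cand$frame[k]; a <- cand$from[k]
    daughters <- succ(f, a)$to
    ## parent chain: walk back while the chain is a clean 1-1 sequence
    steps <- 0L
    cf <- f; cl <- a
    while (cf > 1L) {
      pr <- pred(cf, cl)
      if (nrow(pr) != 1L) break
      if (odeg(cf - 1L, pr$from) != 1L) break
      if (ideg(cf, cl) != 1L) break
      cf <- cf - 1L; cl <- pr$from; steps <- steps + 1L
    }
    pre_s <- steps * dt
    if (pre_s < min_pre_s) next
    ## daughter chains: walk forward until merge/death/end
    sep_frames <- integer(length(daughters))
    node_paths <- vector("list", length(daughters))
    ok <- TRUE
    for (di in seq_along(daughters)) {
      cf <- f + 1L; cl <- daughters[di]
      if (ideg(cf, cl) > 1L) { ok <- FALSE; break }  # born merged
      path <- edge_key(cf, cl)
      while (cf < nfr) {
        sc <- succ(cf, cl)
        if (!nrow(sc)) break                          # died
        sc <- sc[order(-sc$overlap_px, sc$to), , drop = FALSE]
        nxt <- sc$to[1]
        if (ideg(cf + 1L, nxt) > 1L) break            # merged with something
        cf <- cf + 1L; cl <- nxt
        path <- c(path, edge_key(cf, cl))
        if ((cf - f) * dt >= min_post_s + dt) break   # window satisfied
      }
      sep_frames[di] <- cf - f
      node_paths[[di]] <- path
    }
    if (!ok) next
    ## mutual separation: chains must not share nodes
    if (length(unique(unlist(node_paths))) != length(unlist(node_paths))) next
    post_s <- min(sep_frames - 1L) * dt
    if (post_s < min_post_s) next
    site <- fission_site(lineage, f, a, daughters)
    res <- rbind(res, data.frame(
      split_frame = f, parent_label = a,
      daughter_labels = paste(daughters, collapse = "/"),
      site_x_um = site[1], site_y_um = site[2],
      pre_duration_s = pre_s, post_separation_s = post_s))
  }
  if (is.null(res)) return(empty)
  res <- res[order(res$split_frame, res$parent_label), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("fission_events", "data.frame")
  res
}

# Constriction-site estimate: centroid of the parent-footprint pixels lying
# on the interface between the two largest daughters (pixels whose nearest
# daughters are closer than 1.5 px apart in distance). Falls back to the
# midpoint of the daughter centroids for degenerate footprints.
fission_site <- function(lineage, f, parent, daughters) {
  px <- lineage$pixel_size_um
  nr <- dim(lineage$labels)[1]
  pm <- lineage$labels[, , f] == parent
  ppix <- which(pm)
  nxt <- lineage$labels[, , f + 1L]
  coords <- function(pix) cbind(((pix - 1L) %/% nr) + 1L, ((pix - 1L) %% nr) + 1L)
  dd <- lapply(daughters[1:2], function(d) {
    dpix <- which(nxt == d)
    if (!length(dpix) || !length(ppix)) return(NULL)
    pc <- coords(ppix); dc <- coords(dpix)
    sq <- outer(pc[, 1], dc[, 1], "-")^2 + outer(pc[, 2], dc[, 2], "-")^2
    sqrt(apply(sq, 1, min))
  })
  if (!is.null(dd[[1]]) && !is.null(dd[[2]])) {
    iface <- abs(dd[[1]] - dd[[2]]) <= 1.5
    if (any(iface)) {
      pc <- coords(ppix)[iface, , drop = FALSE]
      return(c(px_to_um(mean(pc[, 1]), px), px_to_um(mean(pc[, 2]), px)))
    }
  }
  nodes <- lineage$nodes
  dn <- nodes[nodes$frame == f + 1L & nodes$label %in% daughters, , drop = FALSE]
  c(px_to_um(mean(dn$cx_px), px), px_to_um(mean(dn$cy_px), px))
}

#' Score marker presence at fission-event sites
#'
#' An event is marker-positive when any marker-mask pixel lies within
#' `radius_um` of the event site in any frame of the `min_pre_s` window up
#' to and including the split frame (the window in which constriction-site
#' enrichment is expected).
#'
#' @param events a `fission_events` data frame.
#' @param marker_masks logical array `[row, col, frame]`, e.g. from
#'   [top_fraction_mask_stack()].
#' @param pixel_size_um,frame_interval_s calibration of the mask stack.
#' @param radius_um association radius (must be at least one pixel).
#' @param min_pre_s temporal window before the split that is searched.
#' @param column name of the flag column added to `events`.
#' @return `events` with added logical column and `marker_radius_um`.
#' @export
score_marker_presence <- function(events, marker_masks, pixel_size_um,
                                  frame_interval_s, radius_um = 0.25,
                                  min_pre_s = 30, column = "marker_present") {
  if (radius_um < pixel_size_um)
    stopf("radius_um (%g) is smaller than one pixel (%g um)",
          radius_um, pixel_size_um)
  nfr <- dim(marker_masks)[3]
  w <- as.integer(round(min_pre_s / frame_interval_s))
  r_px <- radius_um / pixel_size_um
  present <- logical(nrow(events))
  for (k in seq_len(nrow(events))) {
    f1 <- events$split_frame[k]
    f0 <- max(1L, f1 - w)
    cx <- events$site_x_um[k] / pixel_size_um
    cy <- events$site_y_um[k] / pixel_size_um
    rows <- max(1L, floor(cy - r_px)):min(dim(marker_masks)[1], ceiling(cy + r_px) + 1L)
    cols <- max(1L, floor(cx - r_px)):min(dim(marker_masks)[2], ceiling(cx + r_px) + 1L)
    dy <- (rows - 0.5) - cy
    dx <- (cols - 0.5) - cx
    near <- outer(dy^2, dx^2, "+") <= r_px^2
    for (f in f0:min(f1, nfr)) {
      if (any(marker_masks[rows, cols, f] & near)) { present[k] <- TRUE; break }
    }
  }
  events[[column]] <- present
  events$marker_radius_um <- rep(radius_um, nrow(events))
  events
}

#' Fission rate summaries
#'
#' @param events a `fission_events` data frame (or anything with one row
#'   per event).
#' @param duration_s duration of the observation window in seconds (> 0).
#' @param n_cells number of cells contributing events.
#' @param n_organelles optional mean organelle count, enabling the
#'   per-organelle rate.
#' @return list with `events_per_cell_per_5min` (primary readout) and
#'   `events_per_organelle_per_min` (`NA` when `n_organelles` is missing).
#' @export
fission_rate <- function(events, duration_s, n_cells = 1,
                         n_organelles = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stopf("duration_s must be > 0")
  n <- nrow(events)
  list(
    events_per_cell_per_5min = n / n_cells * (300 / duration_s),
    events_per_organelle_per_min = if (is.null(n_organelles)) NA_real_
    else n / (n_organelles * duration_s / 60))
}
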