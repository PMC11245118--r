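px <- 0.04
dt <- 5

test_that("lineage graph links overlapping labels across frames", {
  # static object: one chain of length n_frames
  labs <- array(0L, c(30, 30, 6))
  for (f in 1:6) labs[, , f] <- matrix(as.integer(disc_image(30, 30, 15, 15, 6)), 30, 30)
  lin <- build_lineage(labs, px, dt)
  expect_equal(nrow(lin$nodes), 6L)
  expect_equal(nrow(lin$edges), 5L)
  expect_true(all(lin$edges$from == 1L & lin$edges$to == 1L))

  # object vanishing at frame 4: chain ends at 3
  labs[, , 4:6] <- 0L
  lin <- build_lineage(labs, px, dt)
  expect_equal(max(lin$edges$frame), 2L)

  # a parent overlapping two next-frame labels has out-degree 2
  labs <- toy_split_stack(n_frames = 3, split_frame = 2)
  lin <- build_lineage(labs, px, dt)
  e2 <- lin$edges[lin$edges$frame == 2L, ]
  expect_equal(sort(e2$to), c(2L, 3L))
})

test_that("fission detection enforces the pre/post persistence windows", {
  # split at frame 7 of 14, dt = 5 s: 30 s on both sides -> one event
  labs <- toy_split_stack(14, 7)
  lin <- build_lineage(labs, px, dt)
  ev <- detect_fission_events(lin)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$split_frame, 7L)
  expect_gte(ev$pre_duration_s, 30)
  expect_gte(ev$post_separation_s, 30)
  # the constriction site sits between the daughters, inside the parent
  expect_equal(ev$site_x_um, 20.5 * px, tolerance = 2 * px)
  expect_equal(ev$site_y_um, 20 * px, tolerance = 3 * px)

  # too little pre-split persistence -> no event
  expect_equal(nrow(detect_fission_events(build_lineage(
    toy_split_stack(13, 6), px, dt))), 0L)

  # daughters re-merging 20 s after the split ("kiss and run") -> no event
  expect_equal(nrow(detect_fission_events(build_lineage(
    toy_split_stack(14, 7, merge_after = 4), px, dt))), 0L)

  expect_error(detect_fission_events(build_lineage(labs, px, 0)),
               "frame_interval_s")
})

test_that("events are invariant to label renumbering and event-free padding", {
  labs <- toy_split_stack(14, 7)
  lin <- build_lineage(labs, px, dt)
  base <- detect_fission_events(lin)

  # renumber labels per frame
  perm <- labs
  perm[perm == 1L] <- 11L; perm[perm == 2L] <- 9L
  perm[perm == 3L] <- 5L; perm[perm == 4L] <- 2L
  ren <- detect_fission_events(build_lineage(perm, px, dt))
  expect_equal(nrow(ren), 1L)
  expect_equal(ren$split_frame, base$split_frame)
  expect_equal(ren$site_x_um, base$site_x_um)

  # append event-free frames
  padded <- array(0L, c(dim(labs)[1:2], 18))
  padded[, , 1:14] <- labs
  for (f in 15:18) padded[, , f] <- labs[, , 14]
  pad <- detect_fission_events(build_lineage(padded, px, dt))
  expect_equal(nrow(pad), 1L)
  expect_equal(pad$split_frame, base$split_frame)
})

test_that("stricter persistence windows never add events", {
  labs <- toy_split_stack(16, 8)
  lin <- build_lineage(labs, px, dt)
  counts <- vapply(c(10, 20, 30, 40, 60), function(w) {
    nrow(detect_fission_events(lin, min_pre_s = w, min_post_s = w))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("marker scoring flags hotspots near the site within the pre-split window", {
  labs <- toy_split_stack(14, 7)
  lin <- build_lineage(labs, px, dt)
  ev <- detect_fission_events(lin)

  masks <- array(FALSE, c(40, 40, 14))
  masks[20, 21, 5] <- TRUE     # at the site, 2 frames before the split
  sc <- score_marker_presence(ev, masks, px, dt, radius_um = 0.25)
  expect_true(sc$marker_present)

  # marker far from the site, or after the split -> absent
  far <- array(FALSE, c(40, 40, 14)); far[5, 5, 6] <- TRUE
  expect_false(score_marker_presence(ev, far, px, dt)$marker_present)
  late <- array(FALSE, c(40, 40, 14)); late[20, 21, 9] <- TRUE
  expect_false(score_marker_presence(ev, late, px, dt)$marker_present)
  expect_false(score_marker_presence(ev, array(FALSE, c(40, 40, 14)),
                                     px, dt)$marker_present)

  expect_error(score_marker_presence(ev, masks, px, dt, radius_um = 0.01),
               "radius")
})

test_that("fission rates scale linearly with the event count", {
  ev6 <- data.frame(split_frame = 1:6)
  r <- fission_rate(ev6, duration_s = 300, n_cells = 1, n_organelles = 30)
  expect_equal(r$events_per_cell_per_5min, 6)
  expect_equal(r$events_per_organelle_per_min, 6 / (30 * 5))
  r12 <- fission_rate(rbind(ev6, ev6), duration_s = 300)
  expect_equal(r12$events_per_cell_per_5min, 12)
  expect_error(fission_rate(ev6, duration_s = 0), "duration")
})
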