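px <- 0.04
dt <- 5

test_that("the gated greedy linker builds the expected tracks", {
  # single object moving 0.1 um/frame
  det <- data.frame(frame = 1:10, label = 1L,
                    x_um = 0.1 * (1:10), y_um = 1)
  tr <- track_organelles(det, dt, max_link_um = 0.5)
  expect_equal(length(unique(tr$track)), 1L)
  expect_equal(nrow(tr), 10L)

  # two static, well-separated objects: two tracks, no identity swap
  det2 <- rbind(data.frame(frame = rep(1:8, each = 2), label = c(1L, 2L),
                           x_um = c(1, 5), y_um = c(1, 5)))
  tr2 <- track_organelles(det2, dt, max_link_um = 0.5)
  st2 <- track_stats(tr2)
  expect_equal(nrow(st2), 2L)
  expect_equal(st2$displacement_um, c(0, 0))

  # a jump beyond the gate terminates the track instead of mis-linking
  det3 <- data.frame(frame = 1:6, label = 1L,
                     x_um = c(0, 0.1, 0.2, 3, 3.1, 3.2), y_um = 0)
  tr3 <- track_organelles(det3, dt, max_link_um = 1)
  expect_equal(length(unique(tr3$track)), 2L)

  expect_error(track_organelles(det, dt, max_link_um = -1), "max_link_um")
})

test_that("short tracks are dropped at the duration threshold", {
  det <- rbind(data.frame(frame = 1:10, label = 1L, x_um = 1, y_um = 1),
               data.frame(frame = 1:3, label = 2L, x_um = 5, y_um = 5))
  tr <- track_organelles(det, frame_interval_s = 1, max_link_um = 0.5)
  # durations: 9 s and 2 s
  expect_equal(nrow(track_stats(filter_tracks(tr, 10))), 0L)
  kept <- track_stats(filter_tracks(tr, 9))
  expect_equal(nrow(kept), 1L)
  expect_identical(filter_tracks(tr, 0), tr)
  expect_equal(nrow(filter_tracks(
    track_organelles(det[det$frame <= 3, ], 1), 10)), 0L)
})

test_that("mean straight velocity is displacement over duration", {
  tr <- data.frame(frame = c(1, 3), x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(mean_straight_velocity(tr, frame_interval_s = 5), 0.5)

  loop <- data.frame(frame = 1:5, x_um = c(0, 1, 1, 0, 0),
                     y_um = c(0, 0, 1, 1, 0))
  expect_equal(mean_straight_velocity(loop, 5), 0)
  st <- track_stats(structure(cbind(track = 1L, loop),
                              class = c("organelle_tracks", "data.frame")),
                    frame_interval_s = 5)
  expect_gt(st$path_length_um, 0)
  expect_equal(st$velocity_um_s, 0)

  expect_error(mean_straight_velocity(tr[1, , drop = FALSE], 5), "two points")
})

test_that("pure drift with no diffusion is recovered exactly", {
  p <- synth_params(field_size_px = c(256L, 256L), n_organelles = 1L,
                    n_frames = 20L, diffusion_coeff_um2_s = 0,
                    drift_speed_um_s = 0.01, fission_rate_per_org_per_min = 0,
                    seed = 5)
  tr <- simulate_trajectories(p)
  det <- tr$trajectories
  det$label <- det$id
  tracks <- track_organelles(det, p$frame_interval_s, max_link_um = 1)
  st <- track_stats(tracks)
  expect_equal(nrow(st), 1L)
  expect_equal(st$velocity_um_s, 0.01, tolerance = 1e-9)
})

test_that("Manders coefficients follow their set-theoretic definitions", {
  a <- matrix(runif(400), 20, 20)
  expect_equal(unname(manders_coefficients(a, a, 0.5, 0.5)), c(1, 1))

  b <- matrix(0, 20, 20); b[1:10, ] <- 2
  c2 <- matrix(0, 20, 20); c2[11:20, ] <- 2
  expect_equal(unname(manders_coefficients(b, c2, 0.1, 0.1)), c(0, 0))

  # A's support strictly inside B's support
  big <- matrix(0, 20, 20); big[5:16, 5:16] <- 1
  small <- matrix(0, 20, 20); small[8:12, 8:12] <- 1
  mm <- manders_coefficients(small, big, 0.1, 0.1)
  expect_equal(unname(mm["M1"]), 1)
  expect_equal(unname(mm["M2"]), 25 / 144)

  expect_error(manders_coefficients(b, c2, 5, 5), "no signal")
})

test_that("autocorrelation curve is 1 for a static stack and 0 for vanished signal", {
  p <- synth_params(field_size_px = c(96L, 96L), n_organelles = 6L,
                    n_frames = 6L, diffusion_coeff_um2_s = 0,
                    fission_rate_per_org_per_min = 0,
                    photon_scale = Inf, read_noise_sd = 0, seed = 2)
  rs <- render_stack(simulate_trajectories(p))
  cv <- autocorrelation_curve(rs$stack)
  expect_equal(cv$value, rep(1, 6))
  expect_true(all(cv$value >= 0 & cv$value <= 1))
  expect_equal(cv$offset_s, seq(0, 25, by = 5))

  # signal in frame 1, disjoint signal later -> 0 at every positive offset
  frames <- array(0, c(20, 20, 3))
  frames[2:6, 2:6, 1] <- 1
  frames[14:18, 14:18, 2:3] <- 1
  cv0 <- autocorrelation_curve(frames, threshold = 0.5, frame_interval_s = 5)
  expect_equal(cv0$value[-1], c(0, 0))

  expect_error(autocorrelation_curve(array(0, c(10, 10, 3)), threshold = 0.5,
                                     frame_interval_s = 5), "first frame")
})

test_that("mobility summaries aggregate per cell and per timepoint", {
  vel <- data.frame(velocity_um_s = c(0.1, 0.3, 0.2),
                    cell = c("c1", "c1", "c2"), condition = "wt")
  s <- summarize_mobility(velocities = vel)
  expect_equal(s$velocity$conditions$mean, mean(c(0.2, 0.2)))

  curve <- data.frame(offset_s = c(0, 5, 10), m1 = 1, m2 = 1,
                      value = c(1, 0.8, 0.6))
  s2 <- summarize_mobility(curves = list(wt = list(c1 = curve, c2 = curve)))
  expect_equal(s2$curves$sem, rep(0, 3))
  expect_equal(s2$curves$mean, curve$value)
  s1 <- summarize_mobility(curves = list(wt = list(c1 = curve)))
  expect_equal(s1$curves$mean, curve$value)
})
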