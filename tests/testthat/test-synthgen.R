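test_that("parameter validation rejects impossible configurations", {
  expect_error(synth_params(n_frames = 1L), "n_frames")
  expect_error(synth_params(acer_enrichment_prob = 1.2), "probabilities")
  expect_error(synth_params(fission_rate_per_org_per_min = -1), "rates")
  expect_error(synth_params(pixel_size_um = 0), "pixel_size_um")
  # persistence windows cannot fit in a 40 s movie
  p <- synth_params(n_frames = 8L, fission_rate_per_org_per_min = 2)
  expect_error(simulate_trajectories(p), "persistence")
})

test_that("zero motion and no events freeze every centroid", {
  p <- synth_params(field_size_px = c(96L, 96L), n_organelles = 5L,
                    n_frames = 8L, diffusion_coeff_um2_s = 0,
                    drift_speed_um_s = 0, fission_rate_per_org_per_min = 0,
                    seed = 9)
  tr <- simulate_trajectories(p)$trajectories
  for (id in unique(tr$id)) {
    expect_equal(length(unique(tr$x_um[tr$id == id])), 1L)
    expect_equal(length(unique(tr$y_um[tr$id == id])), 1L)
  }
})

test_that("a scheduled fission respects the persistence windows by construction", {
  found <- FALSE
  for (seed in 1:10) {
    p <- synth_params(field_size_px = c(128L, 128L), n_organelles = 1L,
                      n_frames = 60L, fission_rate_per_org_per_min = 2,
                      seed = seed)
    tr <- simulate_trajectories(p)
    fe <- tr$fission_events
    if (nrow(fe) != 1L) next
    found <- TRUE
    f <- fe$frame[1]
    t3 <- tr$trajectories
    parent_frames <- t3$frame[t3$id == fe$parent[1]]
    d1_frames <- t3$frame[t3$id == fe$daughter1[1]]
    d2_frames <- t3$frame[t3$id == fe$daughter2[1]]
    expect_true(all(parent_frames <= f))
    expect_true(all(d1_frames > f))
    expect_gte((f - min(parent_frames)) * p$frame_interval_s, p$min_pre_s)
    expect_gte((max(d1_frames) - f - 1) * p$frame_interval_s, p$min_post_s)
    expect_gte((max(d2_frames) - f - 1) * p$frame_interval_s, p$min_post_s)
    # the site lies inside the field
    fw <- p$field_size_px * p$pixel_size_um
    expect_true(fe$x_um[1] > 0 && fe$x_um[1] < fw[2])
    expect_true(fe$y_um[1] > 0 && fe$y_um[1] < fw[1])
    break
  }
  expect_true(found)
})

test_that("Brownian steps recover the diffusion coefficient (MSD closed form)", {
  p <- synth_params(field_size_px = c(2000L, 2000L), n_organelles = 1L,
                    n_frames = 1001L, diffusion_coeff_um2_s = 0.01,
                    fission_rate_per_org_per_min = 0, seed = 13)
  tr <- simulate_trajectories(p)$trajectories
  steps2 <- diff(tr$x_um)^2 + diff(tr$y_um)^2
  # one-lag MSD = 4 D dt for free 2-D diffusion
  expect_equal(mean(steps2) / p$frame_interval_s, 4 * 0.01, tolerance = 0.1)
})

test_that("identical parameters and seed give bit-identical stacks", {
  p <- synth_params(field_size_px = c(96L, 96L), n_organelles = 6L,
                    n_frames = 16L, fission_rate_per_org_per_min = 0.3,
                    seed = 21)
  a <- render_stack(simulate_trajectories(p))
  b <- render_stack(simulate_trajectories(p))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$labels, b$labels)
  p2 <- p; p2$seed <- 22L
  expect_false(identical(render_stack(simulate_trajectories(p2))$stack$data,
                         a$stack$data))
})

test_that("connected components change by +1 at fissions and -1 at fusions", {
  p <- synth_params(n_organelles = 20L, fission_rate_per_org_per_min = 0.15,
                    kiss_and_run_n = 2L, seed = 31)
  tr <- simulate_trajectories(p)
  labs <- true_label_stack(tr)
  comps <- vapply(seq_len(dim(labs)[3]), function(f) {
    max(orgadyn:::label_components(labs[, , f] > 0))
  }, numeric(1))
  dc <- diff(comps)
  expected <- integer(length(dc))
  for (f in tr$fission_events$frame) expected[f] <- expected[f] + 1L
  for (f in tr$fusion_events$frame) expected[f - 1L] <- expected[f - 1L] - 1L
  expect_equal(dc, expected)
  expect_gt(nrow(tr$fission_events), 0)
  expect_gt(nrow(tr$fusion_events), 0)
})

test_that("rendering conserves intensity and reproduces masks in the noise-free limit", {
  p <- synth_params(field_size_px = c(160L, 160L), n_organelles = 8L,
                    n_frames = 4L, fission_rate_per_org_per_min = 0,
                    photon_scale = Inf, read_noise_sd = 0, seed = 8)
  rs <- render_stack(simulate_trajectories(p))
  for (f in 1:4) {
    img <- rs$stack$data[, , "organelle", f]
    truth <- rs$labels[, , f] > 0
    # total blurred signal tracks total true area within 2%
    expect_equal(sum(img) / sum(truth), 1, tolerance = 0.02)
    # half-max threshold recovers the true mask within a 1 px boundary band
    est <- img > 0.5 * max(img)
    grown <- EBImage::dilate(truth, EBImage::makeBrush(3, "box")) > 0
    shrunk <- EBImage::erode(truth, EBImage::makeBrush(3, "box")) > 0
    expect_true(all(est[!grown] == FALSE))
    expect_true(all(est[shrunk]))
  }
})

test_that("certain enrichment paints every fission site into the marker mask", {
  p <- synth_params(n_organelles = 20L, fission_rate_per_org_per_min = 0.2,
                    acer_enrichment_prob = 1, seed = 17)
  tr <- simulate_trajectories(p)
  rs <- render_stack(tr, p)
  fe <- tr$fission_events
  expect_gt(nrow(fe), 0)
  for (k in seq_len(nrow(fe))) {
    f <- fe$frame[k]
    mask <- top_fraction_mask(rs$stack$data[, , "acer", f], 0.25)
    col <- round(fe$x_um[k] / p$pixel_size_um + 0.5)
    row <- round(fe$y_um[k] / p$pixel_size_um + 0.5)
    win <- mask[max(1, row - 2):min(nrow(mask), row + 2),
                max(1, col - 2):min(ncol(mask), col + 2)]
    expect_true(any(win))
  }
})

test_that("the random marker background covers the stated fraction of organelle area", {
  fracs <- vapply(1:10, function(seed) {
    p <- synth_params(field_size_px = c(192L, 192L), n_organelles = 20L,
                      n_frames = 3L, fission_rate_per_org_per_min = 0,
                      acer_enrichment_prob = 0, seed = seed)
    rs <- render_stack(simulate_trajectories(p))
    num <- 0; den <- 0
    for (f in 1:3) {
      org <- rs$labels[, , f] > 0
      mk <- top_fraction_mask(rs$stack$data[, , "acer", f], 0.25)
      num <- num + sum(org & mk); den <- den + sum(org)
    }
    num / den
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.2), 0.03)
})

test_that("synthetic stacks round-trip through the on-disk format", {
  p <- synth_params(field_size_px = c(64L, 64L), n_organelles = 3L,
                    n_frames = 3L, fission_rate_per_org_per_min = 0, seed = 2)
  rs <- render_stack(simulate_trajectories(p))
  base <- file.path(tempdir(), "synthrt")
  write_synth_timelapse(rs, base)
  expect_identical(read_label_stack(paste0(base, "_labels.tif")), rs$labels)
  s1 <- read_timelapse(base)
  write_timelapse(s1, paste0(base, "2"))
  s2 <- read_timelapse(paste0(base, "2"))
  expect_identical(s1$data, s2$data)    # storage round-trip is exact
  expect_equal(s1$pixel_size_um, p$pixel_size_um)
})
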