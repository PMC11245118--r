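px <- 0.04

test_that("vesicle preprocessing removes flat background and hot pixels", {
  cfg <- vesicle_config(rolling_ball_radius_px = 10)
  expect_equal(preprocess_vesicle_frame(matrix(3, 64, 64), cfg),
               matrix(0, 64, 64))

  img <- matrix(0.1, 64, 64)
  img[30, 30] <- 10
  out <- preprocess_vesicle_frame(img, vesicle_config(rolling_ball_radius_px = 0,
                                                      median_radius_px = 0,
                                                      contrast = FALSE))
  expect_lt(out[30, 30], 10 * 0.05)  # despeckle kills the single hot pixel

  expect_error(preprocess_vesicle_frame(matrix(1, 30, 30), vesicle_config()),
               "rolling-ball")
})

test_that("preprocessing does not degrade blob contrast on a ramp background", {
  set.seed(1)
  ramp <- matrix(rep(seq(0, 0.5, length.out = 128), each = 128), 128, 128)
  img <- ramp + disc_image(128, 128, 64, 64, 9, value = 1)
  blob <- disc_image(128, 128, 64, 64, 7) > 0
  bg <- disc_image(128, 128, 64, 64, 20) == 0
  contrast <- function(x) {
    x <- (x - min(x)) / max(1e-12, diff(range(x)))
    mean(x[blob]) - mean(x[bg])
  }
  out <- preprocess_vesicle_frame(img, vesicle_config(rolling_ball_radius_px = 25))
  expect_gte(contrast(out), contrast(img))
})

test_that("size filter drops components below the calibrated minimum area", {
  m <- matrix(FALSE, 60, 60)
  m[2:32, 2] <- TRUE                 # 31 px  = 0.0496 um^2 -> dropped
  m[2:45, 50] <- TRUE                # 44 px  = 0.0704 um^2 -> kept
  out <- size_filter(m, px)
  expect_false(any(out[, 2]))
  expect_true(all(out[2:45, 50]))

  expect_equal(size_filter(matrix(FALSE, 5, 5), px), matrix(FALSE, 5, 5))
  expect_identical(size_filter(m, px, min_area_um2 = 0), m)
})

test_that("marker-controlled splitting separates touching discs along the intensity valley", {
  xy <- expand.grid(1:80, 1:80)
  d1 <- sqrt((xy[, 2] - 30)^2 + (xy[, 1] - 40)^2)
  d2 <- sqrt((xy[, 2] - 52)^2 + (xy[, 1] - 40)^2)
  img <- matrix(pmax(exp(-d1^2 / 200), exp(-d2^2 / 200)), 80, 80)
  mask <- matrix(d1 <= 14 | d2 <= 14, 80, 80)  # ~20% overlapping discs
  lab <- split_touching(mask, img)
  expect_equal(max(lab), 2L)
  expect_identical(lab > 0, mask)
  truth <- matrix(ifelse(d1 < d2, 1L, 2L), 80, 80)
  agree <- max(mean(lab[mask] == truth[mask]), mean(lab[mask] == 3L - truth[mask]))
  expect_gte(agree, 0.95)

  # single disc, single peak -> one label identical to the mask
  one <- matrix(exp(-d1^2 / 200), 80, 80)
  m1 <- matrix(d1 <= 14, 80, 80)
  lab1 <- split_touching(m1, one)
  expect_equal(max(lab1), 1L)
  expect_identical(lab1 > 0, m1)

  # prominence above the dynamic range -> no seeds, components preserved
  lab2 <- split_touching(mask, img, maxima_prominence = 2)
  expect_equal(max(lab2), 1L)
})

test_that("region morphometrics are calibrated and near-exact on reference shapes", {
  # digital disc of radius 50 px: circularity ~ 1 before clamping
  disc <- matrix(as.integer(disc_image(120, 120, 60, 60, 50)), 120, 120)
  r <- analyze_regions(disc, 1)
  expect_equal(r$area_um2, sum(disc), tolerance = 1e-12)
  expect_gt(r$circularity_raw, 0.95)
  expect_lt(r$circularity_raw, 1.05)
  expect_lte(r$circularity, 1)

  # 100 px at 0.04 um/px -> 0.16 um^2
  sq <- matrix(0L, 20, 20); sq[5:14, 5:14] <- 1L
  expect_equal(analyze_regions(sq, px)$area_um2, 0.16)

  # elongated bar is far less circular than a disc
  bar <- matrix(0L, 20, 80); bar[9:11, 10:69] <- 1L
  expect_lt(analyze_regions(bar, px)$circularity_raw, 0.5)

  expect_equal(nrow(analyze_regions(matrix(0L, 5, 5), px)), 0L)
})

test_that("morphometrics are translation- and 90-degree-rotation invariant", {
  m <- matrix(0L, 90, 90)
  m <- orgadyn:::draw_capsule(m, 40, 45, 0.4, 18, 6, 1L)
  m <- matrix(as.integer(m), 90, 90)
  base <- analyze_regions(m, px)
  shifted <- analyze_regions(orgadyn:::mat_shift(m, 7, -9, 0L), px)
  rotated <- analyze_regions(t(m[nrow(m):1, ]), px)
  for (col in c("area_um2", "perimeter_um", "circularity_raw")) {
    expect_equal(shifted[[col]], base[[col]], tolerance = 1e-9)
    expect_equal(rotated[[col]], base[[col]], tolerance = 0.02)
  }
})

test_that("raising the minimum area never increases the object count", {
  set.seed(5)
  m <- matrix(runif(96 * 96) > 0.82, 96, 96)
  counts <- vapply(c(0, 0.005, 0.01, 0.03, 0.06, 0.12), function(a) {
    max(orgadyn:::label_components(size_filter(m, px, a)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mitochondrial segmentation recovers tubule networks", {
  expect_equal(max(mito_segment(matrix(1, 128, 128), px)), 0L)

  # two disjoint straight tubules
  img <- matrix(0, 128, 128)
  img <- orgadyn:::draw_capsule(img, 35, 35, 0.3, 28, 3, 1)
  img <- orgadyn:::draw_capsule(img, 90, 90, -0.8, 28, 3, 1)
  truth <- img > 0
  img <- EBImage::gblur(img, 1.25)
  lab <- mito_segment(img, px)
  expect_equal(max(lab), 2L)
  expect_gte(sum(lab > 0 & truth) / sum(truth), 0.95)

  # noise-free branched network: foreground covers >= 95% of the true mask
  p <- synth_params(field_size_px = c(160L, 160L), n_organelles = 7L,
                    n_frames = 2L, organelle_shape = "network",
                    fission_rate_per_org_per_min = 0,
                    photon_scale = Inf, read_noise_sd = 0, seed = 4)
  rs <- render_stack(simulate_trajectories(p))
  lab <- mito_segment(get_frame(rs$stack, 1, "organelle"), px)
  truth <- rs$labels[, , 1] > 0
  expect_gte(sum(lab > 0 & truth) / sum(truth), 0.95)
})
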