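#' Parameters for the synthetic time-lapse generator
#'
#' Bundles every knob of the simulator with defaults that emulate a typical
#' Airyscan-style live-cell acquisition of vesicular organelles: 40 nm
#' pixels, a 5 s frame interval and a 5 minute movie (60 frames), so that
#' the 30 s fission persistence windows are an exact 6 frames.
#'
#' Organelles are hard discs (or capsule-shaped tubules) undergoing
#' Brownian motion with optional constant drift, reflected at the field
#' boundaries and kept from interpenetrating by a minimum surface gap.
#' Fission events are scheduled as a Poisson process with
#' `fission_rate_per_org_per_min`, restricted to frames where both
#' persistence windows fit inside the movie; a scheduled split replaces the
#' parent by two area-conserving daughters placed on a random axis through
#' the parent centre. Kiss-and-run artifacts (splits that re-merge after
#' `kiss_separation_s`, i.e. before `min_post_s` expires) can be injected
#' to exercise the false-positive guard of the event detector.
#'
#' The ER-actin marker channel is rendered as a static field of bright
#' sub-micron patches whose Boolean coverage equals
#' `acer_background_fraction`, over a dim ER-like texture; each true
#' fission site is additionally painted with a bright hotspot during the
#' `min_pre_s` window before the split with probability
#' `acer_enrichment_prob`. Camera noise is Poisson at `photon_scale`
#' photons per unit intensity followed by Gaussian read noise.
#'
#' @param field_size_px integer pair, image rows and columns.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_s seconds between frames.
#' @param n_frames number of frames (>= 2).
#' @param n_organelles number of organelles at frame 1.
#' @param organelle_shape `"disc"`, `"tubule"` or `"network"`.
#' @param mean_radius_um,radius_sd_um disc radius distribution (truncated
#'   normal).
#' @param tubule_length_um,tubule_width_um capsule geometry for the tubule
#'   and network shapes.
#' @param diffusion_coeff_um2_s 2-D diffusion coefficient D; the Brownian
#'   step per axis has standard deviation `sqrt(2 * D * dt)`.
#' @param drift_speed_um_s constant drift speed; each organelle gets a
#'   persistent random direction.
#' @param fission_rate_per_org_per_min,fusion_rate_per_org_per_min event
#'   rates (>= 0).
#' @param daughter_separation_speed_um_s active separation drift of
#'   fission daughters along the split axis, applied for `min_post_s`
#'   after the split (fission daughters are transported apart rather than
#'   re-colliding by diffusion); not applied to kiss-and-run daughters.
#' @param kiss_and_run_n number of injected kiss-and-run sequences.
#' @param kiss_separation_s seconds between a kiss-and-run split and its
#'   re-merge (default 20 s, inside the 30 s disqualification window).
#' @param min_pre_s,min_post_s persistence windows that scheduled fissions
#'   must satisfy (parent single before, daughters separate after).
#' @param acer_enrichment_prob probability a true fission site is painted
#'   with a marker hotspot.
#' @param acer_background_fraction Boolean coverage of the random marker
#'   patch field (also the expected fraction of organelle area overlapped
#'   by the thresholded marker mask by chance).
#' @param acer_background_radius_um radius of a background marker patch.
#' @param acer_hotspot_radius_um radius of a fission-site hotspot.
#' @param min_gap_um minimum surface-to-surface gap enforced between
#'   organelles (keeps true label masks 8-connectivity-separate).
#' @param psf_sigma_um Gaussian point-spread sigma.
#' @param photon_scale photons per unit intensity (`Inf` = no shot noise).
#' @param read_noise_sd Gaussian read noise sd (intensity units).
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical stacks.
#' @return an object of class `synth_params`.
#' @seealso [simulate_trajectories()], [render_stack()]
#' @export
synth_params <- function(field_size_px = c(256L, 256L),
                         pixel_size_um = 0.04,
                         frame_interval_s = 5,
                         n_frames = 60L,
                         n_organelles = 30L,
                         organelle_shape = c("disc", "tubule", "network"),
                         mean_radius_um = 0.3,
                         radius_sd_um = 0.05,
                         tubule_length_um = 1.5,
                         tubule_width_um = 0.2,
                         diffusion_coeff_um2_s = 2e-4,
                         drift_speed_um_s = 0,
                         fission_rate_per_org_per_min = 0.13,
                         fusion_rate_per_org_per_min = 0,
                         daughter_separation_speed_um_s = 0.015,
                         kiss_and_run_n = 0L,
                         kiss_separation_s = 20,
                         min_pre_s = 30,
                         min_post_s = 30,
                         acer_enrichment_prob = 0.95,
                         acer_background_fraction = 0.2,
                         acer_background_radius_um = 0.75,
                         acer_hotspot_radius_um = 0.25,
                         min_gap_um = 0.12,
                         psf_sigma_um = 0.05,
                         photon_scale = 500,
                         read_noise_sd = 0.01,
                         seed = 1L) {
  organelle_shape <- match.arg(organelle_shape)
  p <- as.list(environment())
  rates <- c(fission_rate_per_org_per_min, fusion_rate_per_org_per_min,
             diffusion_coeff_um2_s, drift_speed_um_s,
             daughter_separation_speed_um_s)
  if (any(rates < 0)) stopf("rates and motion coefficients must be >= 0")
  probs <- c(acer_enrichment_prob, acer_background_fraction)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (n_frames < 2L) stopf("n_frames must be >= 2")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  if (n_organelles < 1L) stopf("n_organelles must be >= 1")
  if (kiss_and_run_n < 0L) stopf("kiss_and_run_n must be >= 0")
  structure(p, class = "synth_params")
}

#' @export
print.synth_params <- function(x, ...) {
  cat(sprintf(
    "<synth_params> %dx%d px @ %.3g um, %d frames @ %.3g s, %d %ss\n",
    x$field_size_px[1], x$field_size_px[2], x$pixel_size_um, x$n_frames,
    x$frame_interval_s, x$n_organelles, x$organelle_shape))
  cat(sprintf("  D = %.3g um^2/s, drift = %.3g um/s, fission %.3g /org/min, seed %d\n",
              x$diffusion_coeff_um2_s, x$drift_speed_um_s,
              x$fission_rate_per_org_per_min, as.integer(x$seed)))
  invisible(x)
}

# split frames (the last frame at which the parent exists) compatible with
# the persistence windows
eligible_split_frames <- function(p) {
  dt <- p$frame_interval_s
  f0 <- ceiling(p$min_pre_s / dt) + 1L
  f1 <- p$n_frames - 1L - ceiling(p$min_post_s / dt)
  if (f0 > f1) integer(0) else seq.int(f0, f1)
}

#' Simulate organelle trajectories with scheduled fission and fusion
#'
#' Runs the hard-disc Brownian/drift dynamics described in [synth_params()]
#' and returns the complete ground truth: per-frame per-organelle
#' positions, every scheduled fission (with its site and whether a marker
#' hotspot will be painted there), every fusion (including kiss-and-run
#' re-merges), all in calibrated units. Scheduled fissions always satisfy
#' the persistence windows: the parent exists unbranched for at least
#' `min_pre_s` before the split and the daughters stay separate for at
#' least `min_post_s` after; daughters never undergo further events.
#'
#' @param params a [synth_params()] object.
#' @return an object of class `ground_truth`: list with `trajectories`
#'   (data frame: frame, id, x_um, y_um, radius_um, theta, half_len_um),
#'   `fission_events` (frame = split frame, site, parent, daughter ids,
#'   `acer_painted`, `kiss_and_run`), `fusion_events`, and `params`.
#' @export
simulate_trajectories <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  with_seed(p$seed, simulate_trajectories_impl(p))
}

simulate_trajectories_impl <- function(p) {
  dt <- p$frame_interval_s
  nfr <- p$n_frames
  fw <- c(p$field_size_px[2], p$field_size_px[1]) * p$pixel_size_um # (x, y)
  gap <- p$min_gap_um
  tubular <- p$organelle_shape == "tubule"
  n_events_requested <- p$fission_rate_per_org_per_min > 0 ||
    p$fusion_rate_per_org_per_min > 0 || p$kiss_and_run_n > 0
  if (p$organelle_shape == "network" && n_events_requested)
    stopf("fission/fusion events are not supported for the network shape")
  elig <- eligible_split_frames(p)
  if (n_events_requested && !length(elig))
    stopf("n_frames too small: persistence windows (%g s + %g s) do not fit a %g s movie",
          p$min_pre_s, p$min_post_s, (nfr - 1) * dt)

  ## --- initial population -------------------------------------------------
  n <- p$n_organelles
  if (p$organelle_shape == "network")
    return(simulate_network_impl(p))
  radius <- pmin(pmax(rnorm(n, p$mean_radius_um, p$radius_sd_um),
                      0.8 * p$mean_radius_um), 1.5 * p$mean_radius_um)
  half_len <- if (tubular) rep(p$tubule_length_um / 2, n) else rep(NA_real_, n)
  theta <- if (tubular) runif(n, 0, pi) else rep(NA_real_, n)
  eff_r <- function(r, hl) ifelse(is.na(hl), r, hl + r)
  margin <- eff_r(if (tubular) rep(p$tubule_width_um / 2, n) else radius,
                  half_len) + gap
  x <- runif(n, margin, fw[1] - margin)
  y <- runif(n, margin, fw[2] - margin)
  if (tubular) radius <- rep(p$tubule_width_um / 2, n)
  org <- data.frame(id = seq_len(n), x = x, y = y, r = radius,
                    theta = theta, hl = half_len,
                    active = TRUE, birth = 1L,
                    drift_ux = 0, drift_uy = 0, leash = NA_integer_,
                    sep_ux = 0, sep_uy = 0, sep_until = 0L)
  if (p$drift_speed_um_s > 0) {
    ang <- runif(n, 0, 2 * pi)
    org$drift_ux <- cos(ang); org$drift_uy <- sin(ang)
  }
  next_id <- n + 1L

  ## --- event schedule -----------------------------------------------------
  duration_min <- (nfr - 1) * dt / 60
  n_fis <- min(rpois(1, p$fission_rate_per_org_per_min * n * duration_min), n)
  n_kiss <- min(p$kiss_and_run_n, n - n_fis)
  fis_ids <- if (n_fis + n_kiss > 0) sample.int(n, n_fis + n_kiss) else integer(0)
  kiss_elig <- elig[elig + round(p$kiss_separation_s / dt) <= nfr]
  schedule <- NULL
  if (n_fis > 0)
    schedule <- data.frame(id = fis_ids[seq_len(n_fis)],
                           frame = sample(rep(elig, 2), n_fis),
                           kiss = FALSE)
  if (n_kiss > 0) {
    if (!length(kiss_elig))
      stopf("movie too short to place kiss-and-run events")
    schedule <- rbind(schedule,
                      data.frame(id = fis_ids[n_fis + seq_len(n_kiss)],
                                 frame = sample(rep(kiss_elig, 2), n_kiss),
                                 kiss = TRUE))
  }
  n_fus <- rpois(1, p$fusion_rate_per_org_per_min * n * duration_min)
  fus_frames <- if (n_fus > 0) sort(sample(rep(2:(nfr - 1L), 2), n_fus)) else integer(0)

  ## --- state helpers ------------------------------------------------------
  resolve_overlaps <- function(org) {
    act <- which(org$active)
    if (length(act) < 2) return(reflect(org))
    for (iter in 1:15) {
      moved <- FALSE
      pos <- cbind(org$x[act], org$y[act])
      er <- eff_r(org$r[act], org$hl[act])
      d <- as.matrix(dist(pos))
      tgt <- outer(er, er, "+") + gap
      diag(d) <- Inf
      idx <- which(d < tgt, arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      if (nrow(idx)) {
        moved <- TRUE
        for (k in seq_len(nrow(idx))) {
          i <- act[idx[k, 1]]; j <- act[idx[k, 2]]
          dx <- org$x[j] - org$x[i]; dy <- org$y[j] - org$y[i]
          dd <- sqrt(dx^2 + dy^2)
          if (dd < 1e-9) { dx <- 1; dy <- 0; dd <- 1 }
          need <- (eff_r(org$r[i], org$hl[i]) + eff_r(org$r[j], org$hl[j]) +
                     gap - dd) / 2 + 1e-6
          org$x[i] <- org$x[i] - dx / dd * need
          org$y[i] <- org$y[i] - dy / dd * need
          org$x[j] <- org$x[j] + dx / dd * need
          org$y[j] <- org$y[j] + dy / dd * need
        }
      }
      org <- reflect(org)
      if (!moved) break
    }
    org
  }
  reflect <- function(org) {
    act <- which(org$active)
    er <- eff_r(org$r[act], org$hl[act]) + gap
    for (ax in c("x", "y")) {
      lim <- if (ax == "x") fw[1] else fw[2]
      v <- org[[ax]][act]
      v <- ifelse(v < er, er + (er - v) %% pmax(lim - 2 * er, 1e-6), v)
      v <- ifelse(v > lim - er, lim - er - (v - (lim - er)) %% pmax(lim - 2 * er, 1e-6), v)
      org[[ax]][act] <- v
    }
    org
  }

  traj <- vector("list", nfr)
  record <- function(org, f) {
    a <- org[org$active, , drop = FALSE]
    data.frame(frame = f, id = a$id, x_um = a$x, y_um = a$y,
               radius_um = a$r, theta = a$theta, half_len_um = a$hl)
  }
  fission_events <- NULL
  fusion_events <- NULL
  pending_merge <- NULL  # data.frame(frame, id1, id2)
  step_sd <- sqrt(2 * p$diffusion_coeff_um2_s * dt)

  org <- resolve_overlaps(org)
  traj[[1]] <- record(org, 1L)

  for (t in 2:nfr) {
    ## scheduled fissions whose split frame was t - 1: daughters appear at t,
    ## placed on the parent's frame-(t-1) footprint before any motion so the
    ## parent -> daughter temporal overlap is guaranteed by construction
    newborn <- integer(0)
    if (!is.null(schedule)) {
      due <- which(schedule$frame == t - 1L)
      for (k in due) {
        i <- which(org$id == schedule$id[k])
        if (!length(i) || !org$active[i]) next
        site <- c(org$x[i], org$y[i])
        ang <- runif(1, 0, 2 * pi)
        painted <- rbinom(1, 1, p$acer_enrichment_prob) == 1
        if (tubular) {
          hl_d <- org$hl[i] / 2 - gap / 2
          ux <- cos(org$theta[i]); uy <- sin(org$theta[i])
          off <- org$hl[i] / 2 + gap
          d1 <- c(org$x[i] - ux * off, org$y[i] - uy * off)
          d2 <- c(org$x[i] + ux * off, org$y[i] + uy * off)
          newr <- c(org$r[i], org$r[i]); newhl <- c(hl_d, hl_d)
          newth <- c(org$theta[i], org$theta[i])
        } else {
          rd <- org$r[i] / sqrt(2)
          off <- rd + gap / 2 + 0.02
          d1 <- site + c(cos(ang), sin(ang)) * off
          d2 <- site - c(cos(ang), sin(ang)) * off
          newr <- c(rd, rd); newhl <- c(NA_real_, NA_real_)
          newth <- c(NA_real_, NA_real_)
        }
        ids <- c(next_id, next_id + 1L)
        newborn <- c(newborn, ids)
        next_id <- next_id + 2L
        org$active[i] <- FALSE
        org <- rbind(org, data.frame(
          id = ids, x = c(d1[1], d2[1]), y = c(d1[2], d2[2]), r = newr,
          theta = newth, hl = newhl, active = TRUE, birth = t,
          drift_ux = rep(org$drift_ux[i], 2), drift_uy = rep(org$drift_uy[i], 2),
          leash = NA_integer_,
          sep_ux = if (schedule$kiss[k]) c(0, 0) else c(cos(ang), -cos(ang)),
          sep_uy = if (schedule$kiss[k]) c(0, 0) else c(sin(ang), -sin(ang)),
          sep_until = if (schedule$kiss[k]) c(0L, 0L) else
            rep(t - 1L + as.integer(ceiling(p$min_post_s / dt)), 2)))
        fission_events <- rbind(fission_events, data.frame(
          frame = t - 1L, x_um = site[1], y_um = site[2],
          parent = org$id[i], daughter1 = ids[1], daughter2 = ids[2],
          acer_painted = painted, kiss_and_run = schedule$kiss[k]))
        if (schedule$kiss[k]) {
          mf <- t - 1L + as.integer(round(p$kiss_separation_s / dt))
          pending_merge <- rbind(pending_merge, data.frame(
            frame = mf, id1 = ids[1], id2 = ids[2]))
          org$leash[org$id %in% ids] <- ids[1]
        }
      }
    }

    ## Brownian + drift (newborn daughters keep their placement this frame)
    act <- setdiff(which(org$active), which(org$id %in% newborn))
    if (length(act)) {
      sep_on <- (org$sep_until[act] >= t) * p$daughter_separation_speed_um_s
      org$x[act] <- org$x[act] + rnorm(length(act), 0, step_sd) +
        (org$drift_ux[act] * p$drift_speed_um_s + org$sep_ux[act] * sep_on) * dt
      org$y[act] <- org$y[act] + rnorm(length(act), 0, step_sd) +
        (org$drift_uy[act] * p$drift_speed_um_s + org$sep_uy[act] * sep_on) * dt
      if (tubular)
        org$theta[act] <- org$theta[act] + rnorm(length(act), 0, 0.1)
    }

    ## kiss-and-run re-merges due at this frame
    if (!is.null(pending_merge)) {
      due <- which(pending_merge$frame == t)
      for (k in due) {
        i <- which(org$id == pending_merge$id1[k])
        j <- which(org$id == pending_merge$id2[k])
        if (!length(i) || !length(j)) next
        cx <- (org$x[i] + org$x[j]) / 2; cy <- (org$y[i] + org$y[j]) / 2
        newr <- sqrt(org$r[i]^2 + org$r[j]^2)
        org$active[c(i, j)] <- FALSE
        org <- rbind(org, data.frame(
          id = next_id, x = cx, y = cy, r = newr,
          theta = NA_real_, hl = NA_real_, active = TRUE, birth = t,
          drift_ux = org$drift_ux[i], drift_uy = org$drift_uy[i],
          leash = NA_integer_, sep_ux = 0, sep_uy = 0, sep_until = 0L))
        fusion_events <- rbind(fusion_events, data.frame(
          frame = t, x_um = cx, y_um = cy,
          parent1 = org$id[i], parent2 = org$id[j], child = next_id))
        next_id <- next_id + 1L
      }
      pending_merge <- pending_merge[pending_merge$frame > t, , drop = FALSE]
    }

    ## spontaneous fusions: merge the closest eligible pair
    nf_here <- sum(fus_frames == t)
    for (k in seq_len(nf_here)) {
      act <- which(org$active & is.na(org$leash))
      young <- (t - org$birth) * dt < p$min_post_s & org$birth > 1L
      prot <- org$id %in% c(if (!is.null(schedule)) schedule$id,
                            if (!is.null(pending_merge)) c(pending_merge$id1, pending_merge$id2))
      act <- act[!young[act] & !prot[act]]
      if (length(act) < 2) next
      pos <- cbind(org$x[act], org$y[act])
      d <- as.matrix(dist(pos)); diag(d) <- Inf
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      i <- act[ij[1]]; j <- act[ij[2]]
      cx <- (org$x[i] + org$x[j]) / 2; cy <- (org$y[i] + org$y[j]) / 2
      newr <- sqrt(org$r[i]^2 + org$r[j]^2)
      org$active[c(i, j)] <- FALSE
      org <- rbind(org, data.frame(
        id = next_id, x = cx, y = cy, r = max(newr, org$r[i] + org$r[j] - newr / 2),
        theta = NA_real_, hl = NA_real_, active = TRUE, birth = t,
        drift_ux = org$drift_ux[i], drift_uy = org$drift_uy[i],
        leash = NA_integer_, sep_ux = 0, sep_uy = 0, sep_until = 0L))
      fusion_events <- rbind(fusion_events, data.frame(
        frame = t, x_um = cx, y_um = cy,
        parent1 = org$id[i], parent2 = org$id[j], child = next_id))
      next_id <- next_id + 1L
    }

    ## leash kiss-and-run daughters so the re-merge stays local
    if (!is.null(pending_merge) && nrow(pending_merge)) {
      for (k in seq_len(nrow(pending_merge))) {
        i <- which(org$id == pending_merge$id1[k])
        j <- which(org$id == pending_merge$id2[k])
        if (!length(i) || !length(j)) next
        dx <- org$x[j] - org$x[i]; dy <- org$y[j] - org$y[i]
        dd <- sqrt(dx^2 + dy^2)
        leash <- org$r[i] + org$r[j] + 3 * gap
        if (dd > leash) {
          pull <- (dd - leash) / 2
          org$x[i] <- org$x[i] + dx / dd * pull; org$y[i] <- org$y[i] + dy / dd * pull
          org$x[j] <- org$x[j] - dx / dd * pull; org$y[j] <- org$y[j] - dy / dd * pull
        }
      }
    }

    org <- resolve_overlaps(org)
    traj[[t]] <- record(org, t)
  }

  structure(list(
    trajectories = do.call(rbind, traj),
    fission_events = if (is.null(fission_events)) empty_fission_truth() else fission_events,
    fusion_events = if (is.null(fusion_events)) empty_fusion_truth() else fusion_events,
    params = p), class = "ground_truth")
}

empty_fission_truth <- function()
  data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
             parent = integer(0), daughter1 = integer(0), daughter2 = integer(0),
             acer_painted = logical(0), kiss_and_run = logical(0))

empty_fusion_truth <- function()
  data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
             parent1 = integer(0), parent2 = integer(0), child = integer(0))

# Static branched-tubule network (used for mitochondrial morphology tests):
# a few random trees of capsule edges, jiggled rigidly per frame.
simulate_network_impl <- function(p) {
  fw <- c(p$field_size_px[2], p$field_size_px[1]) * p$pixel_size_um
  n_nodes <- max(4L, p$n_organelles)
  nx <- runif(n_nodes, 0.15 * fw[1], 0.85 * fw[1])
  ny <- runif(n_nodes, 0.15 * fw[2], 0.85 * fw[2])
  # connect each node to its nearest already-placed node (random tree)
  edges <- NULL
  for (i in 2:n_nodes) {
    d <- sqrt((nx[seq_len(i - 1)] - nx[i])^2 + (ny[seq_len(i - 1)] - ny[i])^2)
    edges <- rbind(edges, c(which.min(d), i))
  }
  traj <- vector("list", p$n_frames)
  step_sd <- sqrt(2 * p$diffusion_coeff_um2_s * p$frame_interval_s)
  ox <- 0; oy <- 0
  for (t in seq_len(p$n_frames)) {
    if (t > 1) { ox <- ox + rnorm(1, 0, step_sd); oy <- oy + rnorm(1, 0, step_sd) }
    traj[[t]] <- data.frame(
      frame = t, id = seq_len(nrow(edges)),
      x_um = (nx[edges[, 1]] + nx[edges[, 2]]) / 2 + ox,
      y_um = (ny[edges[, 1]] + ny[edges[, 2]]) / 2 + oy,
      radius_um = p$tubule_width_um / 2,
      theta = atan2(ny[edges[, 2]] - ny[edges[, 1]],
                    nx[edges[, 2]] - nx[edges[, 1]]),
      half_len_um = sqrt((nx[edges[, 2]] - nx[edges[, 1]])^2 +
                           (ny[edges[, 2]] - ny[edges[, 1]])^2) / 2)
  }
  structure(list(trajectories = do.call(rbind, traj),
                 fission_events = empty_fission_truth(),
                 fusion_events = empty_fusion_truth(),
                 params = p), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d frames, %d organelle-frames, %d fission(s) (%d kiss-and-run), %d fusion(s)\n",
              x$params$n_frames, nrow(x$trajectories),
              nrow(x$fission_events), sum(x$fission_events$kiss_and_run),
              nrow(x$fusion_events)))
  invisible(x)
}

#' Rasterise the true instance label masks of a ground truth
#'
#' @param truth a `ground_truth` from [simulate_trajectories()].
#' @return integer array `[row, col, frame]`; pixel values are organelle
#'   ids (0 = background). For the network shape, edges of one tree share
#'   ids only where capsules overlap; they are fused into connected
#'   instances per frame.
#' @export
true_label_stack <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- truth$params
  px <- p$pixel_size_um
  nr <- p$field_size_px[1]; nc <- p$field_size_px[2]
  out <- array(0L, c(nr, nc, p$n_frames))
  tr <- truth$trajectories
  network <- p$organelle_shape == "network"
  for (f in seq_len(p$n_frames)) {
    m <- matrix(0L, nr, nc)
    rows <- which(tr$frame == f)
    for (k in rows) {
      if (!is.na(tr$half_len_um[k])) {
        m <- draw_capsule(m, tr$x_um[k] / px, tr$y_um[k] / px, tr$theta[k],
                          tr$half_len_um[k] / px, tr$radius_um[k] / px,
                          value = tr$id[k])
      } else {
        m <- draw_disc(m, tr$x_um[k] / px, tr$y_um[k] / px,
                       tr$radius_um[k] / px, value = tr$id[k])
      }
    }
    if (network && any(m > 0)) m <- label_components(m > 0)
    out[, , f] <- m
  }
  out
}

#' Render a ground truth into a noisy two-channel time-lapse
#'
#' Produces the organelle channel (Gaussian-blurred object footprints) and
#' the ER-actin marker channel (static bright patch field of coverage
#' `acer_background_fraction` over a dim ER-like texture, plus hotspots at
#' painted fission sites during the `min_pre_s` window before each split),
#' degraded by Poisson shot noise and Gaussian read noise. True label
#' masks are returned alongside for oracle testing.
#'
#' @param truth a `ground_truth`.
#' @param params the same [synth_params()] used for the simulation.
#' @return an object of class `synth_timelapse`: list with `stack` (a
#'   [timelapse_stack] with channels `organelle` and `acer`), `labels`
#'   (integer array of true instance masks) and `truth`.
#' @export
render_stack <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "ground_truth"))
  p <- params
  with_seed(p$seed + 1000003L, render_stack_impl(truth, p))
}

render_stack_impl <- function(truth, p) {
  px <- p$pixel_size_um
  nr <- p$field_size_px[1]; nc <- p$field_size_px[2]
  nfr <- p$n_frames
  labels <- true_label_stack(truth)
  sigma_px <- p$psf_sigma_um / px

  ## static marker background: Boolean patch field with target coverage
  bg <- matrix(0, nr, nc)
  if (p$acer_background_fraction > 0) {
    r_h <- p$acer_background_radius_um / px
    n_patch <- ceiling(-log(1 - p$acer_background_fraction) * nr * nc /
                         (pi * r_h^2))
    cx <- runif(n_patch, 0, nc); cy <- runif(n_patch, 0, nr)
    for (k in seq_len(n_patch)) bg <- draw_disc(bg, cx[k], cy[k], r_h, 1)
  }
  tex <- EBImage::gblur(matrix(runif(nr * nc), nr, nc), sigma = 3)
  tex <- (tex - min(tex)) / max(1e-12, diff(range(tex)))

  ## hotspot schedule: frames (split - window + 1) .. split at the true site
  window <- max(1L, as.integer(round(p$min_pre_s / p$frame_interval_s)) + 1L)
  ev <- truth$fission_events
  ev <- ev[ev$acer_painted, , drop = FALSE]

  arr <- array(0, c(nr, nc, 2L, nfr))
  for (f in seq_len(nfr)) {
    fp <- (labels[, , f] > 0) * 1
    org <- if (sigma_px > 0) EBImage::gblur(fp, sigma = sigma_px) else fp
    ac <- pmax(0.35 * tex, bg)
    if (nrow(ev)) {
      hot <- ev[ev$frame >= f & ev$frame - window + 1L <= f, , drop = FALSE]
      for (k in seq_len(nrow(hot)))
        ac <- draw_disc(ac, hot$x_um[k] / px, hot$y_um[k] / px,
                        p$acer_hotspot_radius_um / px, 1)
    }
    if (sigma_px > 0) ac <- EBImage::gblur(ac, sigma = sigma_px)
    arr[, , 1, f] <- org
    arr[, , 2, f] <- ac
  }
  if (is.finite(p$photon_scale)) {
    arr[arr < 0] <- 0
    arr[] <- rpois(length(arr), arr * p$photon_scale) / p$photon_scale
  }
  if (p$read_noise_sd > 0)
    arr[] <- arr + rnorm(length(arr), 0, p$read_noise_sd)
  arr[arr < 0] <- 0
  structure(list(
    stack = timelapse_stack(arr, px, p$frame_interval_s,
                            channels = c("organelle", "acer")),
    labels = labels, truth = truth), class = "synth_timelapse")
}

#' @export
print.synth_timelapse <- function(x, ...) {
  cat("<synth_timelapse>\n  ")
  print(x$stack)
  cat(sprintf("  %d true fission event(s), %d fusion(s)\n",
              nrow(x$truth$fission_events), nrow(x$truth$fusion_events)))
  invisible(x)
}

#' Write a rendered synthetic time-lapse plus its ground truth to disk
#'
#' Writes the intensity channels via [write_timelapse()], the label masks
#' via [write_label_stack()] (`<basename>_labels.tif`) and the ground-truth
#' tables as JSON (`<basename>_truth.json`).
#'
#' @param x a `synth_timelapse` from [render_stack()].
#' @param basename path prefix.
#' @return `basename`, invisibly.
#' @export
write_synth_timelapse <- function(x, basename) {
  stopifnot(inherits(x, "synth_timelapse"))
  write_timelapse(x$stack, basename)
  write_label_stack(x$labels, paste0(basename, "_labels.tif"))
  truth <- x$truth
  jsonlite::write_json(
    list(params = unclass(truth$params),
         trajectories = truth$trajectories,
         fission_events = truth$fission_events,
         fusion_events = truth$fusion_events),
    paste0(basename, "_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(basename)
}
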