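#' By-chance overlap probability between organelle and marker masks
#'
#' The fraction of the organelle mask's integrated density overlapped by
#' the marker mask: the organelle mask is the IsoData threshold of the
#' organelle channel, the marker mask is the top-fraction mask of the
#' marker channel, and the ratio of integrated densities of intersection
#' to organelle is the probability that the marker sits on any given piece
#' of organelle "by chance". By default integrated density is evaluated on
#' the binary masks (pixel counts); `weighting = "intensity"` instead sums
#' the organelle-channel intensities, for the reading of integrated
#' density as a sum of grey values.
#'
#' @param organelle_image organelle-channel frame (or 3-D array of
#'   frames, pooled).
#' @param marker_image marker-channel frame(s), same geometry.
#' @param marker_fraction top fraction for the marker mask.
#' @param weighting `"mask"` (pixel counts, default) or `"intensity"`.
#' @return list of class `overlap_estimate`: `p_chance` in [0, 1],
#'   `organelle_px`, `overlap_px`, `weighting`.
#' @export
chance_overlap_probability <- function(organelle_image, marker_image,
                                       marker_fraction = 0.25,
                                       weighting = c("mask", "intensity")) {
  weighting <- match.arg(weighting)
  if (!identical(dim(organelle_image)[1:2], dim(marker_image)[1:2]))
    stopf("organelle and marker images must share geometry")
  if (length(dim(organelle_image)) == 2L) {
    organelle_image <- array(organelle_image, c(dim(organelle_image), 1L))
    marker_image <- array(marker_image, c(dim(marker_image), 1L))
  }
  num <- 0; den <- 0; n_org <- 0L; n_int <- 0L
  for (f in seq_len(dim(organelle_image)[3])) {
    oi <- organelle_image[, , f]
    if (max(oi) == min(oi)) next
    org <- oi > isodata_threshold(oi)
    if (!any(org)) next
    mk <- top_fraction_mask(marker_image[, , f], marker_fraction)
    inter <- org & mk
    n_org <- n_org + sum(org); n_int <- n_int + sum(inter)
    if (weighting == "mask") {
      num <- num + sum(inter); den <- den + sum(org)
    } else {
      num <- num + sum(oi[inter]); den <- den + sum(oi[org])
    }
  }
  if (den == 0) stopf("no organelle signal")
  structure(list(p_chance = num / den, organelle_px = n_org,
                 overlap_px = n_int, weighting = weighting),
            class = "overlap_estimate")
}

#' @export
print.overlap_estimate <- function(x, ...) {
  cat(sprintf("<overlap_estimate> p_chance = %.4f (%s weighting, %d organelle px)\n",
              x$p_chance, x$weighting, x$organelle_px))
  invisible(x)
}

#' By-chance marker presence at randomised control sites
#'
#' Estimates the null probability that the event-scoring operator
#' ([score_marker_presence()]) fires at a site chosen uniformly at random
#' on an organelle, using the same association radius and temporal window
#' as real events. This control-site randomisation measures the chance
#' level of the *same* Bernoulli measurement applied to events, so the
#' observed-vs-expected comparison stays calibrated for any association
#' radius; the mask-overlap estimate ([chance_overlap_probability()])
#' equals it only in the limit of a one-pixel radius.
#'
#' @param labels integer array of organelle instance masks (truth or
#'   segmentation).
#' @param marker_masks logical array from [top_fraction_mask_stack()].
#' @param pixel_size_um,frame_interval_s calibration.
#' @param radius_um,min_pre_s scoring parameters (must match the event
#'   scoring).
#' @param n_sites number of control sites.
#' @param seed RNG seed for site sampling.
#' @return fraction of control sites scored marker-positive.
#' @export
chance_presence_probability <- function(labels, marker_masks, pixel_size_um,
                                        frame_interval_s, radius_um = 0.25,
                                        min_pre_s = 30, n_sites = 200,
                                        seed = 1L) {
  nfr <- dim(labels)[3]
  w <- as.integer(round(min_pre_s / frame_interval_s))
  f_min <- min(w + 1L, nfr)
  with_seed(seed, {
    frames <- sample(f_min:nfr, n_sites, replace = TRUE)
    sites <- lapply(seq_len(n_sites), function(k) {
      m <- labels[, , frames[k]]
      pix <- which(m > 0L)
      if (!length(pix)) return(NULL)
      p <- sample(pix, 1L)
      nr <- dim(labels)[1]
      data.frame(split_frame = frames[k],
                 site_x_um = px_to_um(((p - 1L) %/% nr) + 1L, pixel_size_um),
                 site_y_um = px_to_um(((p - 1L) %% nr) + 1L, pixel_size_um))
    })
    sites <- do.call(rbind, sites)
    if (is.null(sites)) stopf("no organelle pixels to sample control sites from")
    scored <- score_marker_presence(sites, marker_masks, pixel_size_um,
                                    frame_interval_s, radius_um, min_pre_s)
    mean(scored$marker_present)
  })
}

#' Observed-vs-expected contingency table
#'
#' Builds the 2x2 table comparing the observed number of marker-positive
#' events against the count expected by chance: the expected row is
#' `round(p_chance * n_events)` with half-up rounding (0.5 rounds away
#' from zero), so both rows sum to `n_events`.
#'
#' @param n_present observed marker-positive events.
#' @param n_events total scored events (> 0).
#' @param p_chance by-chance probability in [0, 1].
#' @return 2x2 integer matrix with rows `observed`, `expected` and columns
#'   `present`, `absent`.
#' @examples
#' build_contingency(24, 25, 0.2)
#' @export
build_contingency <- function(n_present, n_events, p_chance) {
  if (n_events <= 0) stopf("n_events must be > 0")
  if (n_present < 0 || n_present > n_events)
    stopf("n_present must be in [0, n_events]")
  if (p_chance < 0 || p_chance > 1) stopf("p_chance must be in [0, 1]")
  exp_present <- as.integer(floor(p_chance * n_events + 0.5))
  matrix(as.integer(c(n_present, n_events - n_present,
                      exp_present, n_events - exp_present)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("observed", "expected"),
                         c("present", "absent")))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with all margins fixed: the two-sided p-value
#' is the sum of the probabilities of every table (with the same margins)
#' whose probability does not exceed that of the observed table, with a
#' relative tie tolerance of 1e-7. Computation is on log-probabilities via
#' `dhyper`, so it is stable for large counts. A table with any zero
#' margin carries no information and returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integers.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2, 2))
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be nonnegative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("table has a zero margin; p = 1")
    return(1)
  }
  m <- cs[1]; nn <- cs[2]; k <- rs[1]
  x <- tab[1, 1]
  support <- max(0L, k - nn):min(k, m)
  lp <- dhyper(support, m, nn, k, log = TRUE)
  lobs <- dhyper(x, m, nn, k, log = TRUE)
  sum(exp(lp[lp <= lobs + log(1 + 1e-7)]))
}

#' One-sample exact binomial comparison
#'
#' A statistically cleaner alternative to the observed-vs-expected Fisher
#' comparison: tests the observed marker-positive count directly against
#' the chance proportion, without discretising the expectation into a
#' pseudo-count row. Reported alongside the Fisher p-value, never silently
#' substituted for it.
#'
#' @inheritParams build_contingency
#' @return two-sided exact binomial p-value.
#' @export
presence_binomial_test <- function(n_present, n_events, p_chance) {
  if (n_events <= 0) stopf("n_events must be > 0")
  stats::binom.test(n_present, n_events, p = min(max(p_chance, 0), 1))$p.value
}

#' Modified chi-squared comparison of two mean curves
#'
#' Compares two per-timepoint mean curves with standard errors via the
#' statistic `sum_t (mA_t - mB_t)^2 / (semA_t^2 + semB_t^2)`, referred to
#' the chi-squared distribution with one degree of freedom per shared
#' timepoint. Identical curves give statistic 0 and p = 1.
#'
#' @param curve_a,curve_b data frames with columns `offset_s`, `mean`,
#'   `sem` on identical timepoint grids; `sem` must be positive.
#' @return object of class `curve_comparison`: `statistic`, `df`,
#'   `p_value` and the per-timepoint table.
#' @export
modified_chi_squared <- function(curve_a, curve_b) {
  need <- c("offset_s", "mean", "sem")
  if (!all(need %in% names(curve_a)) || !all(need %in% names(curve_b)))
    stopf("curves need columns offset_s, mean, sem")
  if (nrow(curve_a) != nrow(curve_b) ||
      any(abs(curve_a$offset_s - curve_b$offset_s) > 1e-9))
    stopf("timepoint grids differ")
  if (any(curve_a$sem <= 0) || any(curve_b$sem <= 0))
    stopf("SEMs must be positive")
  contrib <- (curve_a$mean - curve_b$mean)^2 / (curve_a$sem^2 + curve_b$sem^2)
  stat <- sum(contrib)
  df <- nrow(curve_a)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 table = data.frame(offset_s = curve_a$offset_s,
                                    mean_a = curve_a$mean, sem_a = curve_a$sem,
                                    mean_b = curve_b$mean, sem_b = curve_b$sem,
                                    contribution = contrib)),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("<curve_comparison> X2 = %.4g on %d timepoints, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-level per-cell aggregation
#'
#' The cell is the unit of analysis: values are first averaged within each
#' cell, then cells are averaged within each condition, so unbalanced
#' per-cell observation counts do not weight the condition mean. The
#' condition spread is the standard deviation across cell means; a
#' condition with fewer than two cells has `sd = NA` and is flagged.
#'
#' @param records data frame with a value column plus cell and condition
#'   identifiers.
#' @param value_col name of the value column.
#' @param cell_col,condition_col identifier column names.
#' @return list with `cells` (per-cell means) and `conditions`
#'   (mean, sd, n_cells, sd_defined).
#' @export
aggregate_per_cell <- function(records, value_col,
                               cell_col = "cell",
                               condition_col = "condition") {
  stopifnot(all(c(value_col, cell_col, condition_col) %in% names(records)))
  key <- interaction(records[[condition_col]], records[[cell_col]], drop = TRUE)
  cells <- data.frame(
    condition = tapply(as.character(records[[condition_col]]), key, `[`, 1),
    cell = tapply(as.character(records[[cell_col]]), key, `[`, 1),
    mean = as.numeric(tapply(records[[value_col]], key, mean)),
    n = as.integer(tapply(records[[value_col]], key, length)))
  rownames(cells) <- NULL
  conds <- split(cells$mean, cells$condition)
  conditions <- data.frame(
    condition = names(conds),
    mean = vapply(conds, mean, numeric(1)),
    sd = vapply(conds, function(v) if (length(v) >= 2) sd(v) else NA_real_,
                numeric(1)),
    n_cells = vapply(conds, length, integer(1)))
  conditions$sd_defined <- conditions$n_cells >= 2L
  rownames(conditions) <- NULL
  list(cells = cells, conditions = conditions)
}

#' Ordinary one-way ANOVA on per-cell means
#'
#' Classical equal-variance one-way analysis of variance (between/within
#' decomposition), as used for comparing per-cell summary values across
#' conditions.
#'
#' @param values numeric vector of per-cell means.
#' @param groups condition labels (same length).
#' @return list: `F`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2)) stopf("each group needs at least two values")
  ot <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ot$statistic),
       df_between = unname(ot$parameter[1]),
       df_within = unname(ot$parameter[2]),
       p_value = unname(ot$p.value))
}
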