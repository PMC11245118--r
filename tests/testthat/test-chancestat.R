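test_that("chance overlap is the mask-ratio of integrated densities", {
  org <- matrix(0, 50, 50)
  org[1:40, 1:25] <- 1                      # 1000 px organelle
  mk <- matrix(0, 50, 50)
  mk[1:10, 1:25] <- 1                       # 250 px inside the organelle
  est <- chance_overlap_probability(org, mk)
  expect_equal(est$p_chance, 0.25)

  # disjoint marker -> 0
  mk2 <- matrix(0, 50, 50); mk2[45:50, 30:50] <- 1
  expect_equal(chance_overlap_probability(org, mk2)$p_chance, 0)

  # invariance to intensity rescaling of either channel
  expect_equal(chance_overlap_probability(3 * org + 0, 10 * mk)$p_chance, 0.25)

  expect_error(chance_overlap_probability(matrix(0, 5, 5), matrix(0, 5, 5)),
               "no organelle signal|degenerate")
})

test_that("contingency tables round the expected count half-up", {
  expect_identical(build_contingency(24, 25, 0.2),
                   matrix(c(24L, 1L, 5L, 20L), 2, byrow = TRUE,
                          dimnames = list(c("observed", "expected"),
                                          c("present", "absent"))))
  expect_equal(build_contingency(3, 25, 0)[2, ],
               c(present = 0L, absent = 25L))
  expect_equal(unname(build_contingency(3, 25, 0.5)[2, 1]), 13L)
  expect_error(build_contingency(1, 0, 0.2), "n_events")
  expect_error(build_contingency(5, 4, 0.2), "n_present")
})

test_that("Fisher exact test matches closed forms and independent implementations", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "margin")
  expect_equal(p0, 1)

  set.seed(11)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)
    expect_equal(p, oracle_fisher_exact(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # symmetry under simultaneous row and column swaps
    expect_equal(p, fisher_exact(tab[2:1, 2:1]), tolerance = 1e-12)
  }
})

test_that("binomial alternative matches the exact binomial test", {
  expect_equal(presence_binomial_test(24, 25, 0.2),
               binom.test(24, 25, 0.2)$p.value)
})

test_that("modified chi-squared compares curves per timepoint", {
  a <- data.frame(offset_s = c(5, 10, 15), mean = c(1, 0.8, 0.6),
                  sem = c(0.05, 0.05, 0.05))
  same <- modified_chi_squared(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$df, 3)

  # single timepoint with difference equal to the combined SEM -> statistic 1
  one_a <- data.frame(offset_s = 5, mean = 0, sem = 0.3)
  one_b <- data.frame(offset_s = 5, mean = sqrt(0.3^2 + 0.4^2), sem = 0.4)
  one <- modified_chi_squared(one_a, one_b)
  expect_equal(one$statistic, 1, tolerance = 1e-12)
  expect_equal(one$df, 1)

  b <- a; b$offset_s <- c(5, 10, 20)
  expect_error(modified_chi_squared(a, b), "grids")
  c <- a; c$sem[2] <- 0
  expect_error(modified_chi_squared(a, c), "SEM")
})

test_that("aggregation treats the cell as the unit of analysis", {
  rec <- data.frame(value = c(1, 3, 4, 4, 2, 6),
                    cell = c("c1", "c1", "c2", "c2", "c2", "c2"),
                    condition = "wt")
  agg <- aggregate_per_cell(rec, "value")
  expect_equal(sort(agg$cells$mean), c(2, 4))
  expect_equal(agg$conditions$mean, 3)   # unweighted by per-cell counts
  expect_equal(agg$conditions$sd, sd(c(2, 4)))

  single <- aggregate_per_cell(rec[1:2, ], "value")
  expect_equal(single$conditions$mean, 2)
  expect_true(is.na(single$conditions$sd))
  expect_false(single$conditions$sd_defined)
})

test_that("one-way ANOVA behaves classically", {
  g <- rep(c("a", "b"), each = 4)
  v <- c(1, 2, 3, 4, 1, 2, 3, 4)
  same <- one_way_anova(v, g)
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)

  set.seed(2)
  v2 <- c(rnorm(6), rnorm(6, 1))
  g2 <- rep(c("a", "b"), each = 6)
  a2 <- one_way_anova(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a2$p_value, tt$p.value, tolerance = 1e-9)
  shifted <- one_way_anova(v2 + 100, g2)
  expect_equal(shifted$F, a2$F, tolerance = 1e-9)

  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least two")
})
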