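cells_at <- function(ap, brain = "b1") {
  n <- length(ap)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)), ap_mm = ap,
             dv_um = rep(1000, n), ml_um = rep(1200, n),
             pathway = rep("MC", n), markers = rep("RN", n),
             brain_id = rep(brain, length.out = max(n, 0)),
             slice_id = rep("s1", n))
}

test_that("rostro-caudal binning uses 13 bins, boundary rule, conservation", {
  edges <- ap_bin_edges()
  expect_length(edges, 14)
  centers <- seq(-3.08, -4.28, by = -0.1)
  d <- bin_counts_along_ap(cells_at(centers))
  expect_true(all(d$counts == 1))
  expect_equal(ncol(d$counts), 13)

  # a cell exactly at the rostral limit falls in the first bin
  d1 <- bin_counts_along_ap(cells_at(-3.08))
  expect_equal(unname(d1$counts[1, 1]), 1)

  # conservation: in-range + out-of-range = total
  ap <- c(centers, -2.5, -5.0)
  d2 <- bin_counts_along_ap(cells_at(ap))
  expect_equal(sum(d2$counts) + sum(d2$out_of_range), length(ap))
  expect_equal(unname(d2$out_of_range["b1"]), 2L)

  # empty table: all-zero counts, no error
  d0 <- bin_counts_along_ap(cells_at(numeric(0)))
  expect_true(all(d0$counts == 0))
})

test_that("per-brain normalization scales to each brain's max and is idempotent", {
  cells <- rbind(cells_at(c(-3.1, -3.2, -3.2, -3.3, -3.3, -3.3, -3.3), "b1"),
                 cells_at(rep(c(-3.1, -3.2), c(10, 20)), "b2"))
  d <- normalize_per_brain(bin_counts_along_ap(cells))
  expect_equal(max(d$normalized["b1", ]), 1)
  expect_equal(max(d$normalized["b2", ]), 1)
  expect_equal(unname(d$normalized["b2", 1:2]), c(0.5, 1))
  # scaling one brain's counts leaves its normalized vector unchanged
  d7 <- d; d7$counts["b2", ] <- d$counts["b2", ] * 7L
  expect_equal(normalize_per_brain(d7)$normalized["b2", ],
               d$normalized["b2", ])
  expect_equal(normalize_per_brain(d)$normalized, d$normalized)
})

test_that("distribution battery reports KS, rank-sum, Kruskal-Wallis, Bonferroni", {
  x <- seq(-4, -3, length.out = 10)
  same <- compare_distributions(list(a = x, b = x, c = x))
  expect_equal(same$omnibus$method, "kruskal_wallis")
  expect_equal(same$omnibus$p, 1)
  expect_true(all(same$pairwise$p_bonferroni > 0.99))
  # Bonferroni is min(1, p * n_pairs)
  expect_equal(same$pairwise$p_bonferroni,
               pmin(1, same$pairwise$p_raw * nrow(same$pairwise)))

  set.seed(21)
  shifted <- compare_distributions(list(a = rnorm(100, 0, 0.1),
                                        b = rnorm(100, 5, 0.1),
                                        c = rnorm(100, 10, 0.1)))
  expect_lt(shifted$omnibus$p, 1e-3)
  expect_true(all(shifted$pairwise$p_bonferroni < 0.01))

  two <- compare_distributions(list(a = rnorm(50), b = rnorm(50) + 3))
  expect_equal(two$omnibus$method, "wilcoxon_rank_sum")
  tiny <- compare_distributions(list(a = rnorm(20), b = rnorm(20), c = 1))
  expect_identical(tiny$excluded, "c")
})

test_that("proportion summaries reproduce the worked percentages", {
  expect_equal(proportion_summary(84, 384)$percent_rounded, 21.9)
  expect_equal(proportion_summary(41, 119, digits = 0)$percent_rounded, 34)
  expect_equal(proportion_summary(0, 200)$percent, 0)
  expect_equal(proportion_summary(84, 384)$percent, 100 * 84 / 384)
  expect_error(proportion_summary(5, 0), "positive")
})

test_that("per-group proportions exclude underpowered groups with reasons", {
  den <- data.frame(slice = rep(c("s1", "s2", "s3"), c(40, 30, 2)))
  num <- data.frame(slice = rep(c("s1", "s2"), c(10, 6)))
  ps <- proportion_summary(num, den, group_by = "slice", min_n = 10)
  expect_identical(ps$excluded_groups$group, "s3")
  expect_identical(ps$excluded_groups$reason, "below_min_n")
  expect_equal(nrow(ps$per_group), 2)
  expect_equal(ps$per_group$percent, c(25, 20))
  expect_equal(ps$mean_percent, 22.5)
})

test_that("two-proportion sample size matches a simulation oracle within 1", {
  n <- min_slice_n_for_power(0.1, 0.9)
  expect_lte(n, 10)
  # monotone in effect size
  expect_gte(min_slice_n_for_power(0.3, 0.5), min_slice_n_for_power(0.1, 0.9))
  # Monte-Carlo oracle: smallest n whose simulated pooled-z power >= 0.8
  sim_power <- function(n, p1, p2, reps = 3000) {
    set.seed(123)
    x1 <- rbinom(reps, n, p1); x2 <- rbinom(reps, n, p2)
    ph1 <- x1 / n; ph2 <- x2 / n; pp <- (x1 + x2) / (2 * n)
    z <- abs(ph1 - ph2) / sqrt(pmax(2 * pp * (1 - pp) / n, 1e-12))
    mean(z > qnorm(0.975))
  }
  p1 <- 0.2; p2 <- 0.6
  n_impl <- min_slice_n_for_power(p1, p2)
  n_mc <- which(vapply(2:60, sim_power, numeric(1), p1 = p1, p2 = p2) >= 0.8)[1] + 1
  expect_lte(abs(n_impl - n_mc), 1)
})

test_that("convergence statistics z-score pairs and compute fold differences", {
  eq <- matrix(5, 3, 13, dimnames = list(c("MC+BC", "BC+Bs", "MC+Bs"), NULL))
  expect_warning(cs <- convergence_stats(eq), "identical")
  expect_true(all(cs$z == 0))
  expect_equal(cs$fold_difference, 1)

  m <- rbind("MC+BC" = rep(2.3 * 4, 13), "BC+Bs" = rep(4, 13))
  cs2 <- convergence_stats(m, group_a = "MC+BC", group_b = "BC+Bs")
  expect_equal(cs2$fold_difference, 2.3)
  expect_equal(mean(cs2$z), 0, tolerance = 1e-12)
  expect_equal(sd(cs2$z), 1)

  rn <- c("MC+BC" = 400, "BC+Bs" = 500)
  cs3 <- convergence_stats(m, rn)
  expect_equal(cs3$proportions$proportion,
               unname(rowSums(m)) / as.numeric(rn[cs3$proportions$pair]))
})

test_that("planted convergence fractions are recovered from the generator", {
  sim <- gen_soma_tables(synthetic_anatomy_spec(
    n_cells = c(MC = 0, BC = 0, Bs = 0), n_pair_cells = 2000, seed = 31))
  cells <- sim$cells
  for (pair in c("MC+BC", "BC+Bs")) {
    planted <- sim$ground_truth$convergence_fraction[[pair]]
    sel <- cells$pathway == pair
    frac <- mean(has_marker(cells[sel, ], "CVG"))
    band <- binom_band(planted, sum(sel))
    expect_gte(frac, band[1]); expect_lte(frac, band[2])
  }
})

test_that("soma table validation catches missing columns and bad values", {
  expect_error(soma_table(data.frame(cell_id = "c1")), "lacks column")
  bad <- cells_at(-3.5); bad$dv_um <- -4
  expect_error(soma_table(bad), ">= 0")
  bad2 <- cells_at(-3.5); bad2$markers <- ""
  expect_error(soma_table(bad2), "marker")
})
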