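test_that("spec validation rejects impossible generator settings", {
  expect_error(synthetic_ephys_spec(baseline_rate_hz = -1), "positive")
  expect_error(synthetic_ephys_spec(n_trials = 0), "n_trials")
  expect_error(synthetic_ephys_spec(latency_components = list(c(25, 4, 0.5))),
               "sum to 1")
  expect_error(synthetic_opto_spec(fractions = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(synthetic_anatomy_spec(
    covariances = matrix(c(1, 2, 2, 1), 2)), "positive-definite")
  expect_error(synthetic_axon_spec(enrichment_profile = c(PO = -3)), ">= 0")
})

test_that("whisker generator honours degenerate fractions and identity gain", {
  sim0 <- gen_spike_dataset(synthetic_ephys_spec(n_units = 30,
                                                 responsive_fraction = 0,
                                                 n_trials = 5, seed = 2))
  expect_false(any(sim0$ground_truth$responsive))
  expect_true(all(sim0$ground_truth$sign == "none"))

  sim1 <- gen_spike_dataset(synthetic_ephys_spec(n_units = 30,
                                                 evoked_rate_gain = 1,
                                                 n_trials = 5, seed = 2))
  expect_equal(sim1$ground_truth$evoked_rate_hz,
               sim1$ground_truth$baseline_rate_hz)
})

test_that("generated spike times are valid and deterministic under the seed", {
  spec <- synthetic_ephys_spec(n_units = 15, n_trials = 10, seed = 11)
  sim_a <- gen_spike_dataset(spec)
  sim_b <- gen_spike_dataset(spec)
  expect_identical(sim_a$dataset$spikes, sim_b$dataset$spikes)
  expect_identical(sim_a$ground_truth, sim_b$ground_truth)
  st <- sim_a$dataset$spikes
  expect_true(all(st$time_s >= 0 & st$time_s <= sim_a$dataset$session_s))
  expect_false(is.unsorted(st$time_s[st$unit_id == st$unit_id[1]]))

  opto <- gen_opto_dataset(synthetic_opto_spec(n_units = 10, seed = 4))
  opto2 <- gen_opto_dataset(synthetic_opto_spec(n_units = 10, seed = 4))
  expect_identical(opto$mc$spikes, opto2$mc$spikes)
  expect_identical(opto$bc$spikes, opto2$bc$spikes)
})

test_that("evoked-window rate of responsive units matches the planted gain", {
  # baseline 5 Hz, gain 4, 50 trials: expected in-window rate 20 Hz; the
  # pooled estimate must land within 3 Poisson standard errors.
  spec <- synthetic_ephys_spec(n_units = 60, n_trials = 50,
                               baseline_rate_hz = 5, evoked_rate_gain = 4,
                               negative_fraction = 0, seed = 1)
  sim <- gen_spike_dataset(spec)
  gt <- sim$ground_truth
  sp <- split(sim$dataset$spikes$time_s, sim$dataset$spikes$unit_id)
  ev <- sim$dataset$events$time_s
  total <- 0; window_time <- 0
  for (i in which(gt$responsive)) {
    st <- sp[[gt$unit_id[i]]]
    a <- ev + gt$latency_ms[i] / 1000
    b <- a + gt$duration_ms[i] / 1000
    total <- total + sum(findInterval(b, st, left.open = TRUE) -
                           findInterval(a, st, left.open = TRUE))
    window_time <- window_time + sum(b - a)
  }
  rate_hat <- total / window_time
  se <- sqrt(20 / window_time)
  expect_lt(abs(rate_hat - 20), 3 * se)
})

test_that("opto generator labels units per the planted fractions", {
  opto <- gen_opto_dataset(synthetic_opto_spec(
    n_units = 40, fractions = c(mc_only = 0, bc_only = 0, dual = 1, none = 0),
    seed = 3))
  expect_true(all(opto$ground_truth$label == "dual"))
  expect_true(all(opto$ground_truth$latency_mc_ms >= 9 &
                    opto$ground_truth$latency_mc_ms <= 12))
})

test_that("soma generator recovers planted GABA fraction and centroid", {
  spec <- synthetic_anatomy_spec(n_cells = c(MC = 10000, BC = 0, Bs = 0),
                                 convergence_fraction = numeric(0),
                                 gaba_fraction = 0.23, seed = 7)
  sim <- gen_soma_tables(spec)
  cells <- sim$cells
  expect_equal(nrow(cells), 10000)
  frac <- mean(has_marker(cells, "GABA"))
  band <- binom_band(0.23, 10000)
  expect_gte(frac, band[1]); expect_lte(frac, band[2])
  # centroid within 3 standard errors per axis of the planted (1123, 1505)
  for (axis in c("dv_um", "ml_um")) {
    mu <- spec$centroids$MC[[axis]]
    sem <- sd(cells[[axis]]) / sqrt(nrow(cells))
    expect_lt(abs(mean(cells[[axis]]) - mu), 3 * sem)
  }
})

test_that("empty pathways yield empty table sections without error", {
  sim <- gen_soma_tables(synthetic_anatomy_spec(
    n_cells = c(MC = 0, BC = 5, Bs = 0), convergence_fraction = numeric(0),
    seed = 1))
  expect_equal(sum(sim$cells$pathway == "MC"), 0)
  expect_equal(sum(sim$cells$pathway == "BC"), 5)
})

test_that("axon-count generator produces Table-shaped Poisson matrices", {
  zero <- gen_axon_counts(synthetic_axon_spec(
    enrichment_profile = setNames(rep(0, 15), sc_target_nuclei("diencephalon")),
    seed = 1))
  expect_true(all(zero$matrix$counts == 0))

  dien <- gen_axon_counts(synthetic_axon_spec(region = "diencephalon", seed = 2))
  expect_equal(ncol(dien$matrix$counts), 15)
  bs <- gen_axon_counts(synthetic_axon_spec(region = "brainstem", seed = 2))
  expect_equal(ncol(bs$matrix$counts), 7)

  prof <- setNames(c(500, rep(1, 14)), sc_target_nuclei("diencephalon"))
  hot <- gen_axon_counts(synthetic_axon_spec(enrichment_profile = prof, seed = 3))
  expect_equal(names(which.max(colSums(hot$matrix$counts))), "PO")
  expect_true(all(hot$matrix$counts == floor(hot$matrix$counts)))
  expect_true(all(hot$matrix$counts >= 0))

  again <- gen_axon_counts(synthetic_axon_spec(enrichment_profile = prof, seed = 3))
  expect_identical(hot$matrix$counts, again$matrix$counts)
})
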