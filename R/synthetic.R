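# Synthetic-data generators with planted ground truth.
#
# Every generator is deterministic given its spec (which carries an integer
# seed): the seed is split into per-stage substreams by hashing the stage name
# onto an offset, so adding a stage never perturbs the draws of another.

seed_for <- function(seed, stage) {
  offs <- c(ephys = 101L, opto_mc = 211L, opto_bc = 223L, opto_labels = 227L,
            anatomy = 307L, axons = 401L, events = 503L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Specification for a synthetic whisker-stimulation recording session
#'
#' Describes a session of sorted single units recorded while airpuff stimuli
#' are delivered at random inter-stimulus intervals. Units fire as
#' inhomogeneous Poisson processes: a constant baseline rate, multiplied by
#' `evoked_rate_gain` inside a per-unit response window that starts at a
#' latency drawn from a two-component (fast/slow) Gaussian mixture and lasts
#' `response_duration_ms`. A fraction of responsive units is negatively
#' modulated (rate multiplied by `1/evoked_rate_gain` instead).
#'
#' Defaults emulate the awake recording conditions of the study this package
#' quantifies: 100-ms airpuffs at random 1-100 s intervals, roughly a third
#' of units modulated, and a small minority of those suppressed.
#'
#' @param n_units number of single units.
#' @param n_trials number of airpuff stimuli.
#' @param trial_interval_s length-2 range of uniform inter-stimulus intervals
#'   in seconds.
#' @param baseline_rate_hz baseline firing rate (Hz) of every unit.
#' @param responsive_fraction probability that a unit is stimulus modulated.
#' @param evoked_rate_gain multiplicative rate gain in the response window
#'   (must be >= 0; positively modulated units use the gain, negatively
#'   modulated units use its reciprocal).
#' @param latency_components list of `c(mean_ms, sd_ms, weight)` triplets for
#'   the response-latency mixture; weights must sum to 1.
#' @param response_duration_ms duration of the elevated-rate window (ms).
#' @param negative_fraction fraction of *responsive* units that are
#'   negatively modulated.
#' @param seed integer seed; identical specs produce identical datasets.
#' @return an object of class `synthetic_ephys_spec`.
#' @seealso [gen_spike_dataset()]
#' @export
synthetic_ephys_spec <- function(n_units = 100L,
                                 n_trials = 30L,
                                 trial_interval_s = c(1, 100),
                                 baseline_rate_hz = 5,
                                 responsive_fraction = 0.32,
                                 evoked_rate_gain = 4,
                                 latency_components = list(
                                   c(mean_ms = 25, sd_ms = 4, weight = 0.6),
                                   c(mean_ms = 60, sd_ms = 10, weight = 0.4)),
                                 response_duration_ms = 20,
                                 negative_fraction = 0.07,
                                 seed = 1L) {
  if (!is_count(n_units) || !is_count(n_trials) || n_trials < 1)
    stopf("n_units and n_trials must be non-negative counts (n_trials >= 1)")
  if (length(trial_interval_s) != 2L || any(trial_interval_s <= 0) ||
      diff(trial_interval_s) < 0)
    stopf("trial_interval_s must be an increasing positive range")
  if (!is.numeric(baseline_rate_hz) || baseline_rate_hz <= 0)
    stopf("baseline_rate_hz must be positive")
  if (!is_prob(responsive_fraction) || !is_prob(negative_fraction))
    stopf("responsive_fraction and negative_fraction must lie in [0, 1]")
  if (!is.numeric(evoked_rate_gain) || evoked_rate_gain < 0)
    stopf("evoked_rate_gain must be >= 0")
  w <- vapply(latency_components, function(co) unname(co[3]), numeric(1))
  if (abs(sum(w) - 1) > 1e-8)
    stopf("latency component weights must sum to 1 (got %g)", sum(w))
  if (response_duration_ms <= 0) stopf("response_duration_ms must be positive")
  structure(list(n_units = as.integer(n_units), n_trials = as.integer(n_trials),
                 trial_interval_s = trial_interval_s,
                 baseline_rate_hz = baseline_rate_hz,
                 responsive_fraction = responsive_fraction,
                 evoked_rate_gain = evoked_rate_gain,
                 latency_components = latency_components,
                 response_duration_ms = response_duration_ms,
                 negative_fraction = negative_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_ephys_spec")
}

# Truncated-normal latency draw (>= 0.1 ms), vectorized over units.
draw_latencies <- function(n, components) {
  if (n == 0L) return(list(latency_ms = numeric(0), component = integer(0)))
  w <- vapply(components, function(co) unname(co[3]), numeric(1))
  comp <- sample.int(length(components), n, replace = TRUE, prob = w)
  m <- vapply(components, function(co) unname(co[1]), numeric(1))[comp]
  s <- vapply(components, function(co) unname(co[2]), numeric(1))[comp]
  lo <- pnorm(0.1, m, s)
  list(latency_ms = qnorm(runif(n, lo, 1), m, s), component = comp)
}

# Piecewise-constant Poisson spike train: baseline rate over [0, t_end],
# rate multiplied by `gain` inside the (non-overlapping) windows
# [win_start_j, win_end_j). Returns sorted spike times.
sim_unit_spikes <- function(rate, t_end, win_start = numeric(0),
                            win_end = numeric(0), gain = 1) {
  n0 <- rpois(1L, rate * t_end)
  st <- sort(runif(n0, 0, t_end))
  if (length(win_start) == 0L || gain == 1) return(st)
  idx_s <- findInterval(st, win_start)
  inside <- idx_s >= 1L & st < win_end[pmax(idx_s, 1L)]
  if (gain < 1) {
    drop <- inside & runif(length(st)) >= gain
    st <- st[!drop]
  } else {
    extra_n <- rpois(length(win_start), (gain - 1) * rate * (win_end - win_start))
    if (sum(extra_n) > 0) {
      extra <- runif(sum(extra_n)) *
        rep(win_end - win_start, extra_n) + rep(win_start, extra_n)
      st <- sort(c(st, extra))
    }
  }
  st
}

#' Generate a synthetic whisker-stimulation spike dataset
#'
#' Draws stimulus times at random inter-stimulus intervals and, for every
#' unit, an inhomogeneous Poisson spike train whose rate is elevated (or
#' suppressed) in a latency-shifted response window on every trial. Returns
#' the dataset together with the planted per-unit ground truth.
#'
#' @param spec a [synthetic_ephys_spec()].
#' @return a list with elements `dataset` (a [spike_dataset()]) and
#'   `ground_truth` (data frame: `unit_id`, `responsive`, `sign`,
#'   `baseline_rate_hz`, `evoked_rate_hz`, `latency_ms`, `component`,
#'   `duration_ms`).
#' @examples
#' sim <- gen_spike_dataset(synthetic_ephys_spec(n_units = 5, n_trials = 10))
#' table(sim$ground_truth$sign)
#' @export
gen_spike_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ephys_spec"))
  with_seed(seed_for(spec$seed, "ephys"), {
    events <- cumsum(runif(spec$n_trials, spec$trial_interval_s[1],
                           spec$trial_interval_s[2]))
    t_end <- events[length(events)] + 2
    responsive <- runif(spec$n_units) < spec$responsive_fraction
    negative <- responsive & runif(spec$n_units) < spec$negative_fraction
    lat <- draw_latencies(sum(responsive), spec$latency_components)
    latency_ms <- rep(NA_real_, spec$n_units)
    component <- rep(NA_integer_, spec$n_units)
    latency_ms[responsive] <- lat$latency_ms
    component[responsive] <- lat$component
    gain <- ifelse(!responsive, 1,
                   ifelse(negative, 1 / spec$evoked_rate_gain,
                          spec$evoked_rate_gain))
    unit_ids <- sprintf("u%03d", seq_len(spec$n_units))
    spk <- vector("list", spec$n_units)
    for (i in seq_len(spec$n_units)) {
      if (responsive[i]) {
        ws <- events + latency_ms[i] / 1000
        we <- ws + spec$response_duration_ms / 1000
        spk[[i]] <- sim_unit_spikes(spec$baseline_rate_hz, t_end, ws, we, gain[i])
      } else {
        spk[[i]] <- sim_unit_spikes(spec$baseline_rate_hz, t_end)
      }
    }
    spikes <- data.frame(
      unit_id = rep(unit_ids, lengths(spk)),
      time_s = unlist(spk, use.names = FALSE))
    gt <- data.frame(
      unit_id = unit_ids,
      responsive = responsive,
      sign = ifelse(!responsive, "none", ifelse(negative, "negative", "positive")),
      baseline_rate_hz = spec$baseline_rate_hz,
      evoked_rate_hz = spec$baseline_rate_hz * gain,
      latency_ms = latency_ms,
      component = component,
      duration_ms = ifelse(responsive, spec$response_duration_ms, NA_real_))
    list(dataset = spike_dataset(spikes,
                                 events = data.frame(time_s = events,
                                                     label = "whisker"),
                                 session_s = t_end),
         ground_truth = gt)
  })
}

#' Specification for a synthetic dual-site optogenetic session
#'
#' Describes the paired-stimulation design in which motor-cortex (MC) and
#' barrel-cortex (BC) layer 5 are photostimulated in successive blocks while
#' the same SC units are recorded. Units belong to one of four planted
#' classes (`mc_only`, `bc_only`, `dual`, `none`); in a block stimulating a
#' cortex that drives the unit, the baseline Poisson rate is multiplied by
#' `evoked_count_gain` for `response_duration_ms` starting at a latency drawn
#' uniformly from `evoked_latency_ms`.
#'
#' The default gain of 100 on a 5 Hz baseline yields a ~500 Hz burst and so
#' about 3-4.5 evoked spikes inside the fixed 6-18 ms evoked analysis window
#' once the 9-12 ms onset latency is accounted for - a reliable short-latency
#' burst of the kind layer-5 photostimulation produces - which is the
#' "strong response" condition used throughout calibration tests.
#'
#' @param n_units number of units.
#' @param n_trials light pulses per block (default 40).
#' @param pulse_period_s inter-pulse interval in seconds (default 5).
#' @param fractions length-4 numeric `(mc_only, bc_only, dual, none)`
#'   summing to 1.
#' @param evoked_latency_ms length-2 range of evoked first-spike latencies.
#' @param evoked_count_gain multiplicative rate gain in the response window.
#' @param baseline_rate_hz baseline firing rate (Hz).
#' @param response_duration_ms duration of the evoked burst (ms).
#' @param seed integer seed.
#' @return an object of class `synthetic_opto_spec`.
#' @export
synthetic_opto_spec <- function(n_units = 100L,
                                n_trials = 40L,
                                pulse_period_s = 5,
                                fractions = c(mc_only = 0.1, bc_only = 0.1,
                                              dual = 0.05, none = 0.75),
                                evoked_latency_ms = c(9, 12),
                                evoked_count_gain = 100,
                                baseline_rate_hz = 5,
                                response_duration_ms = 12,
                                seed = 1L) {
  if (!is_count(n_units) || !is_count(n_trials) || n_trials < 1)
    stopf("n_units and n_trials must be counts with n_trials >= 1")
  if (pulse_period_s <= 0) stopf("pulse_period_s must be positive")
  if (length(fractions) != 4L || abs(sum(fractions) - 1) > 1e-8 ||
      !is_prob(fractions))
    stopf("fractions must be 4 proportions (mc_only, bc_only, dual, none) summing to 1")
  if (length(evoked_latency_ms) != 2L || diff(evoked_latency_ms) < 0)
    stopf("evoked_latency_ms must be an increasing range")
  if (evoked_count_gain < 0 || baseline_rate_hz <= 0 || response_duration_ms <= 0)
    stopf("gain must be >= 0 and rates/durations positive")
  names(fractions) <- c("mc_only", "bc_only", "dual", "none")
  structure(list(n_units = as.integer(n_units), n_trials = as.integer(n_trials),
                 pulse_period_s = pulse_period_s, fractions = fractions,
                 evoked_latency_ms = evoked_latency_ms,
                 evoked_count_gain = evoked_count_gain,
                 baseline_rate_hz = baseline_rate_hz,
                 response_duration_ms = response_duration_ms,
                 seed = as.integer(seed)),
            class = "synthetic_opto_spec")
}

#' Generate paired MC-stim / BC-stim optogenetic spike datasets
#'
#' @param spec a [synthetic_opto_spec()].
#' @return list with `mc` and `bc` (each a [spike_dataset()] recorded during
#'   stimulation of that cortex) and `ground_truth` (data frame: `unit_id`,
#'   `label`, `drives_mc`, `drives_bc`, `latency_mc_ms`, `latency_bc_ms`).
#' @export
gen_opto_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_opto_spec"))
  unit_ids <- sprintf("u%03d", seq_len(spec$n_units))
  labels <- with_seed(seed_for(spec$seed, "opto_labels"),
    sample(names(spec$fractions), spec$n_units, replace = TRUE,
           prob = spec$fractions))
  drives <- list(mc = labels %in% c("mc_only", "dual"),
                 bc = labels %in% c("bc_only", "dual"))
  events <- seq_len(spec$n_trials) * spec$pulse_period_s
  t_end <- events[length(events)] + 2
  lat <- list(mc = rep(NA_real_, spec$n_units), bc = rep(NA_real_, spec$n_units))
  gen_block <- function(cortex) {
    with_seed(seed_for(spec$seed, paste0("opto_", cortex)), {
      d <- drives[[cortex]]
      lat_ms <- rep(NA_real_, spec$n_units)
      lat_ms[d] <- runif(sum(d), spec$evoked_latency_ms[1],
                         spec$evoked_latency_ms[2])
      spk <- vector("list", spec$n_units)
      for (i in seq_len(spec$n_units)) {
        if (d[i]) {
          ws <- events + lat_ms[i] / 1000
          spk[[i]] <- sim_unit_spikes(spec$baseline_rate_hz, t_end, ws,
                                      ws + spec$response_duration_ms / 1000,
                                      spec$evoked_count_gain)
        } else {
          spk[[i]] <- sim_unit_spikes(spec$baseline_rate_hz, t_end)
        }
      }
      list(dataset = spike_dataset(
             data.frame(unit_id = rep(unit_ids, lengths(spk)),
                        time_s = unlist(spk, use.names = FALSE)),
             events = data.frame(time_s = events,
                                 label = paste0(cortex, "_stim")),
             session_s = t_end),
           latency_ms = lat_ms)
    })
  }
  mc <- gen_block("mc")
  bc <- gen_block("bc")
  gt <- data.frame(unit_id = unit_ids, label = labels,
                   drives_mc = drives$mc, drives_bc = drives$bc,
                   latency_mc_ms = mc$latency_ms, latency_bc_ms = bc$latency_ms)
  list(mc = mc$dataset, bc = bc$dataset, ground_truth = gt)
}

#' Specification for synthetic trans-synaptically labeled soma tables
#'
#' Emulates the labeled recipient-neuron (RN) populations of the anatomy
#' experiments: per-pathway Gaussian soma clouds in the depth (DV) x
#' mediolateral (ML) plane, uniform anterior-posterior (AP) positions over
#' the sampled sectioning range, a planted GABAergic fraction (GABAergic RNs
#' carry the `iRN` marker), and, for each input pair, a convergence
#' population in which each RN is a convergence neuron (`CVG`) with the
#' planted probability. Default centroids and fractions follow the mapped
#' pathways: motor cortex (MC), barrel cortex (BC), trigeminal brainstem (Bs).
#'
#' @param pathways character vector of pathway names.
#' @param centroids named list of `c(dv_um, ml_um)` cloud centers.
#' @param covariances named list of 2x2 positive-definite covariances
#'   (micrometres squared); a single matrix is recycled.
#' @param ap_range_mm length-2 AP sampling range, rostral first (default
#'   -3.08 to -4.28 mm from bregma).
#' @param n_cells named integer vector of cells per pathway.
#' @param gaba_fraction probability a cell is GABAergic (default 0.23).
#' @param convergence_fraction named vector of CVG probabilities per pair
#'   (names like `"MC+BC"`).
#' @param n_pair_cells cells generated per convergence-pair experiment
#'   (default 1000, putting the strongest pair's convergence population at
#'   the few-hundred-neuron scale of the mapped dataset).
#' @param n_brains,n_slices numbers of brains and of 100-um AP slices.
#' @param seed integer seed.
#' @return object of class `synthetic_anatomy_spec`.
#' @export
synthetic_anatomy_spec <- function(pathways = c("MC", "BC", "Bs"),
                                   centroids = list(MC = c(dv_um = 1123, ml_um = 1505),
                                                    BC = c(dv_um = 1035, ml_um = 1297),
                                                    Bs = c(dv_um = 1276, ml_um = 993)),
                                   covariances = diag(c(150^2, 150^2)),
                                   ap_range_mm = c(-3.08, -4.28),
                                   n_cells = c(MC = 400, BC = 400, Bs = 400),
                                   gaba_fraction = 0.23,
                                   convergence_fraction = c("MC+BC" = 0.23,
                                                            "BC+Bs" = 0.10,
                                                            "MC+Bs" = 0.10),
                                   n_pair_cells = 1000L,
                                   n_brains = 3L, n_slices = 13L,
                                   seed = 1L) {
  if (is.matrix(covariances))
    covariances <- setNames(rep(list(covariances), length(pathways)), pathways)
  for (p in pathways) {
    S <- covariances[[p]]
    if (is.null(S) || !isTRUE(all(dim(S) == c(2L, 2L))) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stopf("covariance for pathway %s must be 2x2 positive-definite", p)
    if (is.null(centroids[[p]]) || length(centroids[[p]]) != 2L)
      stopf("centroid for pathway %s must be (dv_um, ml_um)", p)
  }
  if (!is_prob(gaba_fraction) || !is_prob(convergence_fraction))
    stopf("gaba_fraction and convergence_fraction must lie in [0, 1]")
  if (length(ap_range_mm) != 2L || ap_range_mm[1] <= ap_range_mm[2])
    stopf("ap_range_mm must be ordered rostral (greater) to caudal (smaller)")
  if (!all(pathways %in% names(n_cells))) stopf("n_cells must name every pathway")
  structure(list(pathways = pathways, centroids = centroids,
                 covariances = covariances, ap_range_mm = ap_range_mm,
                 n_cells = n_cells, gaba_fraction = gaba_fraction,
                 convergence_fraction = convergence_fraction,
                 n_pair_cells = as.integer(n_pair_cells),
                 n_brains = as.integer(n_brains),
                 n_slices = as.integer(n_slices), seed = as.integer(seed)),
            class = "synthetic_anatomy_spec")
}

rmvnorm2 <- function(n, mu, sigma) {
  z <- matrix(rnorm(2L * n), ncol = 2L)
  sweep(z %*% chol(sigma), 2L, mu, `+`)
}

#' Generate a synthetic soma table with planted labels
#'
#' @param spec a [synthetic_anatomy_spec()].
#' @return list with `cells` (a [soma_table()]) and `ground_truth` (the
#'   planted centroids and fractions, plus the realized convergence-cloud
#'   centers keyed by pair).
#' @export
gen_soma_tables <- function(spec) {
  stopifnot(inherits(spec, "synthetic_anatomy_spec"))
  with_seed(seed_for(spec$seed, "anatomy"), {
    rows <- list()
    mk_cells <- function(pathway, n, mu, sigma, cvg_prob = 0) {
      if (n == 0L) return(NULL)
      xy <- rmvnorm2(n, mu, sigma)
      ap <- runif(n, spec$ap_range_mm[2], spec$ap_range_mm[1])
      gaba <- runif(n) < spec$gaba_fraction
      cvg <- runif(n) < cvg_prob
      markers <- paste0("RN;NeuN",
                        ifelse(gaba, ";GABA;iRN", ""),
                        ifelse(cvg, ";CVG", ""))
      slice <- pmin(spec$n_slices,
                    1L + floor((spec$ap_range_mm[1] - ap) /
                               (diff(rev(spec$ap_range_mm)) / spec$n_slices)))
      data.frame(cell_id = NA_character_, ap_mm = ap,
                 dv_um = pmax(xy[, 1], 0), ml_um = pmax(xy[, 2], 0),
                 pathway = pathway, markers = markers,
                 brain_id = paste0("b", sample.int(spec$n_brains, n, TRUE)),
                 slice_id = paste0("s", slice))
    }
    for (p in spec$pathways) {
      rows[[p]] <- mk_cells(p, spec$n_cells[[p]], spec$centroids[[p]],
                            spec$covariances[[p]])
    }
    cvg_centers <- list()
    for (pair in names(spec$convergence_fraction)) {
      ab <- strsplit(pair, "+", fixed = TRUE)[[1]]
      if (!all(ab %in% spec$pathways)) stopf("unknown pathway in pair %s", pair)
      mu <- (spec$centroids[[ab[1]]] + spec$centroids[[ab[2]]]) / 2
      sig <- (spec$covariances[[ab[1]]] + spec$covariances[[ab[2]]]) / 2
      cvg_centers[[pair]] <- mu
      rows[[pair]] <- mk_cells(pair, spec$n_pair_cells, mu, sig,
                               cvg_prob = spec$convergence_fraction[[pair]])
    }
    cells <- do.call(rbind, rows)
    if (is.null(cells)) {
      cells <- data.frame(cell_id = character(0), ap_mm = numeric(0),
                          dv_um = numeric(0), ml_um = numeric(0),
                          pathway = character(0), markers = character(0),
                          brain_id = character(0), slice_id = character(0))
    }
    rownames(cells) <- NULL
    if (nrow(cells)) cells$cell_id <- sprintf("c%05d", seq_len(nrow(cells)))
    list(cells = soma_table(cells, ap_range_mm = spec$ap_range_mm),
         ground_truth = list(centroids = spec$centroids,
                             gaba_fraction = spec$gaba_fraction,
                             convergence_fraction = spec$convergence_fraction,
                             cvg_centers = cvg_centers))
  })
}

#' Specification for synthetic per-nucleus axon-count matrices
#'
#' Per-nucleus mean counts (the enrichment profile) are modulated along the
#' anterior-posterior axis by a smooth unimodal envelope, and integer counts
#' are drawn as independent Poisson deviates around the per-bin means.
#'
#' @param region `"diencephalon"` (15 target nuclei, AP -1.22 to -2.54 mm) or
#'   `"brainstem"` (7 nuclei, AP -5.4 to -6.4 mm).
#' @param pathway pathway label carried on the output matrix.
#' @param n_ap_bins number of 100-um AP bins (default: region standard).
#' @param enrichment_profile named per-nucleus mean count at the AP envelope
#'   peak; defaults to a profile enriched in a few nuclei.
#' @param seed integer seed.
#' @return object of class `synthetic_axon_spec`.
#' @export
synthetic_axon_spec <- function(region = c("diencephalon", "brainstem"),
                                pathway = "MC-RN",
                                n_ap_bins = NULL,
                                enrichment_profile = NULL,
                                seed = 1L) {
  region <- match.arg(region)
  nuclei <- sc_target_nuclei(region)
  if (is.null(n_ap_bins))
    n_ap_bins <- if (region == "diencephalon") 13L else 10L
  if (!is_count(n_ap_bins) || n_ap_bins < 1) stopf("n_ap_bins must be >= 1")
  if (is.null(enrichment_profile)) {
    enrichment_profile <- setNames(rep(2, length(nuclei)), nuclei)
    hot <- intersect(c("PO", "VM", "ZI", "PF", "LP", "Gi", "PnC", "7N"), nuclei)
    enrichment_profile[hot] <- c(30, 22, 16, 12, 8, 25, 15, 20)[seq_along(hot)]
  }
  if (!all(names(enrichment_profile) %in% nuclei))
    stopf("enrichment_profile names must be nuclei of %s", region)
  full <- setNames(rep(0, length(nuclei)), nuclei)
  full[names(enrichment_profile)] <- enrichment_profile
  if (any(full < 0)) stopf("enrichment means must be >= 0")
  structure(list(region = region, pathway = pathway,
                 n_ap_bins = as.integer(n_ap_bins),
                 enrichment_profile = full, seed = as.integer(seed)),
            class = "synthetic_axon_spec")
}

#' Generate a synthetic axon-count matrix
#'
#' @param spec a [synthetic_axon_spec()].
#' @return list with `matrix` (an [axon_count_matrix()]) and `ground_truth`
#'   (the bins x nuclei matrix of Poisson means).
#' @export
gen_axon_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_axon_spec"))
  with_seed(seed_for(spec$seed, "axons"), {
    m <- spec$n_ap_bins
    envelope <- exp(-((seq_len(m) - (m + 1) / 2)^2) / (2 * (m / 3)^2))
    means <- outer(envelope, spec$enrichment_profile)
    counts <- matrix(rpois(length(means), means), nrow = m,
                     dimnames = list(NULL, names(spec$enrichment_profile)))
    list(matrix = axon_count_matrix(counts, region = spec$region,
                                    pathway = spec$pathway,
                                    n_ap_bins = m),
         ground_truth = means)
  })
}
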