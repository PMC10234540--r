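# Electrophysiology containers and response statistics.

#' Sorted spike dataset
#'
#' Container for a session of sorted single units: a long table of spike
#' times, stimulus event times, and optional probe geometry plus per-channel
#' unit amplitudes for trilateration.
#'
#' @param spikes data frame with columns `unit_id`, `time_s` (seconds,
#'   non-negative; sorted per unit on construction).
#' @param events data frame with columns `time_s`, `label`.
#' @param session_s session duration in seconds (default: last spike/event
#'   plus one second).
#' @param sampling_rate acquisition rate in Hz (default 30000).
#' @param channel_positions optional data frame `channel`, `x_um`, `y_um`.
#' @param unit_amplitudes optional data frame `unit_id`, `channel`, `amp_uv`
#'   of per-channel peak-to-peak amplitudes (non-negative).
#' @return object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, events, session_s = NULL,
                          sampling_rate = 30000,
                          channel_positions = NULL, unit_amplitudes = NULL) {
  stopifnot(is.data.frame(spikes), all(c("unit_id", "time_s") %in% names(spikes)),
            is.data.frame(events), "time_s" %in% names(events))
  if (nrow(spikes) && any(spikes$time_s < 0)) stopf("spike times must be >= 0")
  if (nrow(events) && any(events$time_s < 0)) stopf("event times must be >= 0")
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  if (!"label" %in% names(events)) events$label <- rep("stim", nrow(events))
  if (is.null(session_s))
    session_s <- max(c(spikes$time_s, events$time_s, 0)) + 1
  if (!is.null(unit_amplitudes) && any(unit_amplitudes$amp_uv < 0))
    stopf("amplitudes must be >= 0")
  structure(list(spikes = spikes, events = events,
                 session_s = session_s, sampling_rate = sampling_rate,
                 channel_positions = channel_positions,
                 unit_amplitudes = unit_amplitudes),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("<spike_dataset> %d units, %d spikes, %d events, %.1f s session\n",
              length(unique(x$spikes$unit_id)), nrow(x$spikes),
              nrow(x$events), x$session_s))
  invisible(x)
}

unit_ids <- function(dataset) unique(dataset$spikes$unit_id)

spike_list <- function(dataset) {
  ids <- unit_ids(dataset)
  sp <- split(dataset$spikes$time_s, factor(dataset$spikes$unit_id, levels = ids))
  sp[ids]
}

#' Analysis windows and thresholds for response classification
#'
#' All windows are half-open `[a, b)` in milliseconds relative to stimulus
#' onset. Defaults: whisker spontaneous `[-50, -20)` vs response `[20, 50)`
#' (identical 30-ms lengths); optogenetic spontaneous `[-18, -6)` vs evoked
#' `[6, 18)` (identical 12-ms lengths); per-trial z threshold 1.96
#' (alpha = 5%); null success proportion `p0 = 1/3`; target power 0.8.
#'
#' @param whisker_pre,whisker_post,opto_spont,opto_evoked length-2 windows, ms.
#' @param alpha significance level in (0, 1).
#' @param z_threshold per-trial z-score success threshold.
#' @param p0 null trial-success proportion in (0, 1).
#' @param power target statistical power for trial-number design.
#' @return object of class `response_windows`.
#' @export
response_windows <- function(whisker_pre = c(-50, -20),
                             whisker_post = c(20, 50),
                             opto_spont = c(-18, -6),
                             opto_evoked = c(6, 18),
                             alpha = 0.05, z_threshold = 1.96,
                             p0 = 1 / 3, power = 0.8) {
  chk <- function(w, nm) {
    if (length(w) != 2L || diff(w) <= 0) stopf("%s must be an increasing window", nm)
  }
  chk(whisker_pre, "whisker_pre"); chk(whisker_post, "whisker_post")
  chk(opto_spont, "opto_spont"); chk(opto_evoked, "opto_evoked")
  if (abs(diff(whisker_pre) - diff(whisker_post)) > 1e-9)
    stopf("whisker pre/post windows must have identical length")
  if (abs(diff(opto_spont) - diff(opto_evoked)) > 1e-9)
    stopf("opto spontaneous/evoked windows must have identical length")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (p0 <= 0 || p0 >= 1) stopf("p0 must lie in (0, 1)")
  if (power <= 0 || power >= 1) stopf("power must lie in (0, 1)")
  structure(list(whisker_pre = whisker_pre, whisker_post = whisker_post,
                 opto_spont = opto_spont, opto_evoked = opto_evoked,
                 alpha = alpha, z_threshold = z_threshold, p0 = p0,
                 power = power),
            class = "response_windows")
}

#' Unit quality-control criteria
#'
#' Inclusion thresholds for sorted units: fewer than
#' `max_refractory_violation_fraction` of inter-spike intervals below
#' `refractory_ms`, and a session-wide baseline rate above
#' `min_baseline_rate_hz`.
#'
#' @param max_refractory_violation_fraction maximum tolerated fraction of
#'   inter-spike intervals shorter than the refractory period (default 0.03).
#' @param refractory_ms refractory period in ms (default 1.5).
#' @param min_baseline_rate_hz minimum baseline rate in Hz (default 0.1).
#' @return object of class `qc_criteria`.
#' @export
qc_criteria <- function(max_refractory_violation_fraction = 0.03,
                        refractory_ms = 1.5, min_baseline_rate_hz = 0.1) {
  if (max_refractory_violation_fraction <= 0 || refractory_ms <= 0 ||
      min_baseline_rate_hz <= 0)
    stopf("all QC thresholds must be positive")
  structure(list(max_refractory_violation_fraction = max_refractory_violation_fraction,
                 refractory_ms = refractory_ms,
                 min_baseline_rate_hz = min_baseline_rate_hz),
            class = "qc_criteria")
}

#' Filter units by refractory-period violations and baseline rate
#'
#' A unit is kept when its refractory violation fraction (inter-spike
#' intervals shorter than the refractory period, as a fraction of all
#' intervals; defined as 0 for units with fewer than two spikes) is strictly
#' below the criterion and its session-wide rate is strictly above the
#' minimum.
#'
#' @param dataset a [spike_dataset()].
#' @param criteria a [qc_criteria()].
#' @return list with `dataset` (units passing QC) and `report` (one row per
#'   unit: `unit_id`, `n_spikes`, `rate_hz`, `violation_fraction`, `kept`,
#'   `reason`).
#' @export
qc_filter_units <- function(dataset, criteria = qc_criteria()) {
  stopifnot(inherits(dataset, "spike_dataset"), inherits(criteria, "qc_criteria"))
  sp <- spike_list(dataset)
  n <- lengths(sp)
  viol <- vapply(sp, function(st) {
    if (length(st) < 2L) return(0)
    mean(diff(st) * 1000 < criteria$refractory_ms)
  }, numeric(1))
  rate <- n / dataset$session_s
  ok_viol <- viol < criteria$max_refractory_violation_fraction
  ok_rate <- rate > criteria$min_baseline_rate_hz
  reason <- rep("", length(sp))
  reason[!ok_viol] <- "refractory"
  reason[!ok_rate] <- ifelse(reason[!ok_rate] == "", "rate", "refractory+rate")
  report <- data.frame(unit_id = names(sp), n_spikes = as.integer(n),
                       rate_hz = rate, violation_fraction = viol,
                       kept = ok_viol & ok_rate, reason = reason,
                       row.names = NULL)
  keep_ids <- report$unit_id[report$kept]
  out <- dataset
  out$spikes <- dataset$spikes[dataset$spikes$unit_id %in% keep_ids, , drop = FALSE]
  rownames(out$spikes) <- NULL
  if (!is.null(out$unit_amplitudes))
    out$unit_amplitudes <-
      out$unit_amplitudes[out$unit_amplitudes$unit_id %in% keep_ids, , drop = FALSE]
  list(dataset = out, report = report)
}

#' Per-trial spike counts in a peri-stimulus window
#'
#' Counts spikes of every unit in the half-open window `[a, b)` ms relative
#' to each stimulus onset.
#'
#' @param dataset a [spike_dataset()].
#' @param window_ms length-2 window in ms relative to onset.
#' @return integer matrix, units x trials, with unit ids as row names.
#' @export
trial_spike_counts <- function(dataset, window_ms) {
  stopifnot(inherits(dataset, "spike_dataset"), length(window_ms) == 2L)
  ev <- dataset$events$time_s
  if (length(ev) == 0L) stopf("dataset has no stimulus events")
  sp <- spike_list(dataset)
  starts <- ev + window_ms[1] / 1000
  ends <- ev + window_ms[2] / 1000
  out <- t(vapply(sp, count_in_windows, integer(length(ev)) * 0,
                  starts = starts, ends = ends))
  storage.mode(out) <- "integer"
  out
}

#' Peri-stimulus time histogram
#'
#' Bins spikes of every unit relative to stimulus onsets. Bins are half-open
#' `[left, right)`; if `bin_ms` does not divide the window length the last
#' bin is truncated.
#'
#' @param dataset a [spike_dataset()].
#' @param window_ms peri-stimulus window in ms (default `c(-50, 100)`).
#' @param bin_ms bin width in ms (default 1).
#' @param rate if `TRUE`, convert counts to rates in Hz
#'   (`count / (n_trials * bin_s)`).
#' @param order_by row ordering of the returned matrix: by per-unit median
#'   first-spike latency after onset (`"latency"`, shortest first), by total
#'   in-window response magnitude (`"magnitude"`, largest first), or input
#'   order (`"none"`).
#' @return object of class `psth`: list with `counts` (units x bins matrix),
#'   `bin_edges_ms`, `n_trials`, `unit_order`, `rate`.
#' @export
build_psth <- function(dataset, window_ms = c(-50, 100), bin_ms = 1,
                       rate = FALSE, order_by = c("latency", "magnitude", "none")) {
  order_by <- match.arg(order_by)
  stopifnot(inherits(dataset, "spike_dataset"), bin_ms > 0)
  ev <- dataset$events$time_s
  if (length(ev) == 0L) stopf("dataset has no stimulus events")
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  if (edges[length(edges)] < window_ms[2]) edges <- c(edges, window_ms[2])
  sp <- spike_list(dataset)
  counts <- t(vapply(sp, function(st) {
    rel <- peri_times(st, ev, window_ms)
    tabulate(findInterval(rel, edges, rightmost.closed = FALSE,
                          left.open = FALSE),
             nbins = length(edges) - 1L)
  }, numeric(length(edges) - 1L)))
  ord <- seq_len(nrow(counts))
  if (order_by == "latency") {
    lat <- first_spike_latency(dataset,
                               window_ms = c(max(0, window_ms[1]), window_ms[2]))
    ord <- order(lat$latency_ms, na.last = TRUE)
  } else if (order_by == "magnitude") {
    ord <- order(rowSums(counts), decreasing = TRUE)
  }
  counts <- counts[ord, , drop = FALSE]
  if (rate) counts <- counts / (length(ev) * bin_ms / 1000)
  structure(list(counts = counts, bin_edges_ms = edges,
                 n_trials = length(ev), unit_order = rownames(counts),
                 rate = rate),
            class = "psth")
}

# Spike times relative to the nearest preceding-window event; stimulus
# intervals are assumed longer than the window so windows never overlap.
peri_times <- function(st, ev, window_ms) {
  rel <- numeric(0)
  for (e in ev) {
    a <- e + window_ms[1] / 1000
    b <- e + window_ms[2] / 1000
    i <- findInterval(c(a, b), st, left.open = TRUE)
    if (i[2] > i[1]) rel <- c(rel, (st[(i[1] + 1L):i[2]] - e) * 1000)
  }
  rel
}

#' Per-unit first-spike latency
#'
#' For every trial, the time of the first spike inside the window after
#' stimulus onset; the unit's latency is the median over trials that
#' contained at least one in-window spike, and `NA` when no trial did.
#'
#' @param dataset a [spike_dataset()].
#' @param window_ms window in ms; must start at or after onset.
#' @return data frame with `unit_id`, `latency_ms`, `n_trials_with_spike`.
#' @export
first_spike_latency <- function(dataset, window_ms = c(0, 50)) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (window_ms[1] < 0) stopf("latency window must start at or after onset")
  ev <- dataset$events$time_s
  sp <- spike_list(dataset)
  res <- vapply(sp, function(st) {
    lat <- vapply(ev, function(e) {
      a <- e + window_ms[1] / 1000
      b <- e + window_ms[2] / 1000
      i <- findInterval(a, st, left.open = TRUE)
      if (i < length(st) && st[i + 1L] < b) (st[i + 1L] - e) * 1000 else NA_real_
    }, numeric(1))
    c(if (all(is.na(lat))) NA_real_ else median(lat, na.rm = TRUE),
      sum(!is.na(lat)))
  }, numeric(2))
  data.frame(unit_id = names(sp), latency_ms = res[1, ],
             n_trials_with_spike = as.integer(res[2, ]), row.names = NULL)
}

#' Modulation index
#'
#' Normalized contrast `MI = (R - C) / (R + C)` between the response-window
#' firing rate `R` and the spontaneous-window rate `C`: -1 when `R = 0` and
#' `C != 0`, 0 when `R = C`, +1 when `C = 0` and `R != 0`. Undefined
#' (`NA`) when both rates are zero.
#'
#' @param R,C non-negative firing rates (Hz); vectorized.
#' @return numeric vector of modulation indices in `[-1, 1]`.
#' @examples
#' modulation_index(12, 4)   # 0.5
#' modulation_index(0, 7)    # -1
#' @export
modulation_index <- function(R, C) {
  if (any(R < 0, na.rm = TRUE) || any(C < 0, na.rm = TRUE))
    stopf("rates must be >= 0")
  out <- (R - C) / (R + C)
  out[R == 0 & C == 0] <- NA_real_
  out
}

#' Whisker responsiveness test (two-sample rank-sum on trial counts)
#'
#' Compares per-trial spike counts in the spontaneous window against the
#' response window with a two-sample Wilcoxon (Mann-Whitney) rank-sum test.
#' A unit is responsive when `p < alpha`; the response sign follows the
#' modulation index (positive when the response-window rate exceeds the
#' spontaneous rate). Rates are `total in-window spikes /
#' (n_trials x window length)`.
#'
#' @param dataset a [spike_dataset()].
#' @param windows a [response_windows()].
#' @param p_adjust multiple-testing correction across units applied to the
#'   responsiveness call (`"none"`, the default per-unit convention, or
#'   `"bonferroni"`).
#' @return data frame, one row per unit: `unit_id`, `p_value`, `responsive`,
#'   `sign`, `mi`, `rate_response_hz`, `rate_spont_hz`, `median_pre`,
#'   `median_post`. The per-trial count matrices are attached as attributes
#'   `pre_counts` and `post_counts`.
#' @export
test_whisker_modulation <- function(dataset, windows = response_windows(),
                                    p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(windows, "response_windows"))
  pre <- trial_spike_counts(dataset, windows$whisker_pre)
  post <- trial_spike_counts(dataset, windows$whisker_post)
  if (ncol(pre) < 2L) stopf("need at least 2 trials")
  p <- vapply(seq_len(nrow(pre)), function(i) {
    a <- pre[i, ]; b <- post[i, ]
    if (all(a == a[1]) && all(b == a[1])) return(1)
    suppressWarnings(wilcox.test(b, a)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  win_s <- diff(windows$whisker_post) / 1000
  R <- rowSums(post) / (ncol(post) * win_s)
  C <- rowSums(pre) / (ncol(pre) * win_s)
  mi <- modulation_index(R, C)
  p_call <- if (p_adjust == "bonferroni") pmin(1, p * length(p)) else p
  responsive <- p_call < windows$alpha
  sgn <- rep("none", length(p))
  sgn[responsive & !is.na(mi) & mi > 0] <- "positive"
  sgn[responsive & !is.na(mi) & mi < 0] <- "negative"
  out <- data.frame(unit_id = rownames(pre), p_value = p,
                    responsive = responsive, sign = sgn, mi = mi,
                    rate_response_hz = R, rate_spont_hz = C,
                    median_pre = apply(pre, 1, median),
                    median_post = apply(post, 1, median), row.names = NULL)
  attr(out, "pre_counts") <- pre
  attr(out, "post_counts") <- post
  out
}

#' Per-trial z-scores of optogenetically evoked spike counts
#'
#' For every unit, evoked-window counts are z-scored against the mean and
#' standard deviation of the unit's spontaneous-window counts across trials.
#' Degenerate rule when the spontaneous standard deviation is zero: trials
#' whose evoked count exceeds the spontaneous mean get `+Inf` (counted as
#' successes), trials equal to the mean get 0, trials below it `-Inf`.
#'
#' @param dataset a [spike_dataset()] recorded during one stimulation block.
#' @param windows a [response_windows()].
#' @return numeric matrix, units x trials, of z-scores; spontaneous and
#'   evoked count matrices attached as attributes.
#' @export
opto_trial_zscores <- function(dataset, windows = response_windows()) {
  stopifnot(inherits(windows, "response_windows"))
  spont <- trial_spike_counts(dataset, windows$opto_spont)
  evoked <- trial_spike_counts(dataset, windows$opto_evoked)
  if (ncol(spont) < 2L) stopf("need at least 2 trials")
  mu <- rowMeans(spont)
  s <- apply(spont, 1, sd)
  z <- (evoked - mu) / s
  deg <- s == 0
  if (any(deg)) {
    zd <- sign(evoked[deg, , drop = FALSE] - mu[deg]) * Inf
    zd[evoked[deg, , drop = FALSE] == mu[deg]] <- 0
    z[deg, ] <- zd
  }
  attr(z, "spont_counts") <- spont
  attr(z, "evoked_counts") <- evoked
  z
}

#' Classify units as optogenetically responsive from trial z-scores
#'
#' A trial is a success when its z-score exceeds `z_threshold`. A unit is
#' responsive when a one-tailed one-sample t-test of the per-trial success
#' indicators against the null proportion `p0` rejects at `alpha`
#' (alternative: mean success proportion greater than `p0`). Zero-variance
#' indicator vectors (all successes or all failures) are decided by comparing
#' the success proportion to `p0` directly.
#'
#' @param z units x trials z-score matrix from [opto_trial_zscores()], or a
#'   logical success-indicator matrix.
#' @param windows a [response_windows()] supplying `z_threshold`, `p0`,
#'   `alpha`.
#' @return data frame with `unit_id`, `n_successes`, `success_proportion`,
#'   `p_value`, `responsive`.
#' @export
classify_opto_responsive <- function(z, windows = response_windows()) {
  stopifnot(is.matrix(z), inherits(windows, "response_windows"))
  succ <- if (is.logical(z)) z else z > windows$z_threshold
  n <- ncol(succ)
  prop <- rowMeans(succ)
  p <- vapply(seq_len(nrow(succ)), function(i) {
    x <- as.numeric(succ[i, ])
    if (var(x) == 0) return(if (mean(x) > windows$p0) 0 else 1)
    t.test(x, mu = windows$p0, alternative = "greater")$p.value
  }, numeric(1))
  data.frame(unit_id = rownames(succ) %||% sprintf("u%03d", seq_len(nrow(succ))),
             n_successes = as.integer(rowSums(succ)),
             success_proportion = prop, p_value = p,
             responsive = p < windows$alpha, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify dual-input convergence from paired stimulation blocks
#'
#' Runs the per-trial z-score classification on the motor-cortex and
#' barrel-cortex stimulation blocks of the same units and combines the
#' flags: a unit is dual-responsive exactly when it is responsive to both.
#' Median evoked first-spike latencies are reported per block.
#'
#' @param mc,bc [spike_dataset()]s recorded during MC and BC stimulation.
#' @param windows a [response_windows()].
#' @return data frame with per-cortex success proportions and p-values,
#'   `responsive_mc`, `responsive_bc`, `responsive_dual`, `latency_mc_ms`,
#'   `latency_bc_ms`.
#' @export
classify_dual_input <- function(mc, bc, windows = response_windows()) {
  res_mc <- classify_opto_responsive(opto_trial_zscores(mc, windows), windows)
  res_bc <- classify_opto_responsive(opto_trial_zscores(bc, windows), windows)
  if (!identical(res_mc$unit_id, res_bc$unit_id))
    stopf("MC and BC blocks must contain the same units in the same order")
  lat_win <- c(max(0, windows$opto_evoked[1]), windows$opto_evoked[2])
  lat_mc <- first_spike_latency(mc, lat_win)
  lat_bc <- first_spike_latency(bc, lat_win)
  data.frame(unit_id = res_mc$unit_id,
             success_proportion_mc = res_mc$success_proportion,
             success_proportion_bc = res_bc$success_proportion,
             p_value_mc = res_mc$p_value, p_value_bc = res_bc$p_value,
             responsive_mc = res_mc$responsive,
             responsive_bc = res_bc$responsive,
             responsive_dual = res_mc$responsive & res_bc$responsive,
             latency_mc_ms = lat_mc$latency_ms[match(res_mc$unit_id, lat_mc$unit_id)],
             latency_bc_ms = lat_bc$latency_ms[match(res_mc$unit_id, lat_bc$unit_id)],
             row.names = NULL)
}

# Exact two-sided binomial rejection region at level alpha (alpha/2 per
# tail) for H0: p = p0 with N trials; returns power under p = p1.
exact_binom_power <- function(N, p0, p1, alpha) {
  k <- 0:N
  upper_tail <- 1 - pbinom(k - 1, N, p0)   # P(X >= k | p0)
  lower_tail <- pbinom(k, N, p0)           # P(X <= k | p0)
  k_hi <- k[upper_tail <= alpha / 2]
  k_lo <- k[lower_tail <= alpha / 2]
  pow <- 0
  if (length(k_hi)) pow <- pow + (1 - pbinom(min(k_hi) - 1, N, p1))
  if (length(k_lo)) pow <- pow + pbinom(max(k_lo), N, p1)
  pow
}

#' Trial count required to resolve a success proportion from p0
#'
#' Smallest number of trials `N` such that the exact one-sample binomial
#' test of `H0: p = p0` (two-sided `alpha`, split equally between tails)
#' reaches the target power under a true proportion `p1`. The classical
#' normal-approximation sample size is co-reported for comparison.
#'
#' @param p1 true success proportion in (0, 1).
#' @param p0 null success proportion in (0, 1), different from `p1`.
#' @param power target power (default 0.8).
#' @param alpha two-sided significance level (default 0.05).
#' @param max_n search bound (default 10000).
#' @return list with `n_exact`, `n_normal`, `power_at_n` (exact power
#'   achieved at `n_exact`).
#' @examples
#' required_trial_count(1 / 3, 2 / 3)
#' @export
required_trial_count <- function(p1, p0, power = 0.8, alpha = 0.05,
                                 max_n = 10000L) {
  if (any(c(p1, p0) <= 0) || any(c(p1, p0) >= 1)) stopf("p1, p0 must lie in (0, 1)")
  if (p1 == p0) stopf("p1 must differ from p0 (no finite N otherwise)")
  n_exact <- NA_integer_
  pow_at <- NA_real_
  for (N in seq_len(max_n)) {
    pow <- exact_binom_power(N, p0, p1, alpha)
    if (pow >= power) { n_exact <- N; pow_at <- pow; break }
  }
  if (is.na(n_exact)) stopf("no N <= %d reaches power %.2f", max_n, power)
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n_normal <- ceiling(((za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1))) /
                         (p1 - p0))^2)
  list(n_exact = n_exact, n_normal = as.integer(n_normal), power_at_n = pow_at)
}

#' Sweep the null proportion and track responsive-unit cardinality
#'
#' For each candidate null proportion the number of units classified as
#' responsive is recorded; the curve is non-increasing in `p0`. The selected
#' `p0` is the smallest grid value from which the cardinality changes by at
#' most `tol` units across a sliding window of `window` consecutive grid
#' points - an automated stand-in for visually locating the inflection where
#' the included-unit count stabilizes.
#'
#' @param successes units x trials logical success-indicator matrix (e.g.
#'   `opto_trial_zscores(d) > 1.96`).
#' @param candidate_p0 ascending grid of null proportions in (0, 1).
#' @param alpha significance level of the per-unit one-tailed t-test.
#' @param tol maximum allowed cardinality change within the window
#'   (default 0).
#' @param window number of consecutive grid points over which stability is
#'   required (default 3).
#' @return list with `curve` (data frame `p0`, `n_responsive`) and
#'   `selected_p0` (`NA` when no stable region exists).
#' @export
threshold_sweep <- function(successes, candidate_p0, alpha = 0.05,
                            tol = 0L, window = 3L) {
  if (length(candidate_p0) == 0L) stopf("candidate_p0 grid is empty")
  if (is.unsorted(candidate_p0)) stopf("candidate_p0 must be ascending")
  stopifnot(is.matrix(successes))
  counts <- vapply(candidate_p0, function(p0) {
    w <- response_windows(alpha = alpha, p0 = p0)
    sum(classify_opto_responsive(successes, w)$responsive)
  }, numeric(1))
  sel <- NA_real_
  if (length(counts) >= window) {
    for (i in seq_len(length(counts) - window + 1L)) {
      seg <- counts[i:(i + window - 1L)]
      if (max(seg) - min(seg) <= tol) { sel <- candidate_p0[i]; break }
    }
  }
  list(curve = data.frame(p0 = candidate_p0, n_responsive = counts),
       selected_p0 = sel)
}

#' Localize a unit by amplitude trilateration
#'
#' Estimates the (x, y) position of a unit on the probe plane from its
#' per-channel peak-to-peak amplitudes, assuming amplitude decays with the
#' square of distance, `A(d) = a / d^2`. The `k_channels` largest-amplitude
#' channels are used; for a candidate position the source strength `a` is
#' profiled out in closed form and the squared amplitude error is minimized
#' by Nelder-Mead followed by a BFGS polish, starting from the
#' amplitude-weighted channel centroid. With a degenerate (collinear)
#' geometry and equal amplitudes the weighted centroid is returned with
#' `degenerate = TRUE`.
#'
#' @param channel_positions data frame `channel`, `x_um`, `y_um`.
#' @param amplitudes data frame `channel`, `amp_uv` (or a named numeric
#'   vector keyed by channel).
#' @param k_channels number of top-amplitude channels used (default 4).
#' @return list with `x_um`, `y_um`, `source_strength`, `rss`,
#'   `channels_used`, `degenerate`.
#' @export
trilaterate_unit <- function(channel_positions, amplitudes, k_channels = 4L) {
  stopifnot(all(c("channel", "x_um", "y_um") %in% names(channel_positions)))
  if (is.data.frame(amplitudes)) {
    amp <- setNames(amplitudes$amp_uv, amplitudes$channel)
  } else amp <- amplitudes
  amp <- amp[as.character(channel_positions$channel)]
  amp[is.na(amp)] <- 0
  if (sum(amp > 0) < 3L) stopf("need >= 3 channels with positive amplitude")
  keep <- order(amp, decreasing = TRUE)[seq_len(min(k_channels, sum(amp > 0)))]
  P <- as.matrix(channel_positions[keep, c("x_um", "y_um")])
  A <- as.numeric(amp[keep])
  centroid <- colSums(P * A) / sum(A)
  cen <- sweep(P, 2, colMeans(P))
  degenerate <- all(abs(A - A[1]) < 1e-12) &&
    min(svd(cen)$d) < 1e-9 * max(svd(cen)$d)
  if (degenerate) {
    return(list(x_um = unname(centroid[1]), y_um = unname(centroid[2]),
                source_strength = NA_real_, rss = NA_real_,
                channels_used = channel_positions$channel[keep],
                degenerate = TRUE))
  }
  obj <- function(xy) {
    d2 <- (P[, 1] - xy[1])^2 + (P[, 2] - xy[2])^2
    d2 <- pmax(d2, 1e-12)
    u <- 1 / d2
    a <- sum(A * u) / sum(u * u)       # profiled source strength
    sum((A - a * u)^2)
  }
  fit <- optim(centroid, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  d2 <- pmax((P[, 1] - fit$par[1])^2 + (P[, 2] - fit$par[2])^2, 1e-12)
  u <- 1 / d2
  list(x_um = unname(fit$par[1]), y_um = unname(fit$par[2]),
       source_strength = sum(A * u) / sum(u * u), rss = fit$value,
       channels_used = channel_positions$channel[keep], degenerate = FALSE)
}

#' Trilaterate every unit in a dataset
#'
#' @param dataset a [spike_dataset()] carrying `channel_positions` and
#'   `unit_amplitudes`.
#' @param k_channels channels per fit (default 4).
#' @return data frame `unit_id`, `x_um`, `y_um`, `degenerate`.
#' @export
trilaterate_units <- function(dataset, k_channels = 4L) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (is.null(dataset$channel_positions) || is.null(dataset$unit_amplitudes))
    stopf("dataset lacks channel positions or unit amplitudes")
  ids <- unique(dataset$unit_amplitudes$unit_id)
  rows <- lapply(ids, function(id) {
    a <- dataset$unit_amplitudes[dataset$unit_amplitudes$unit_id == id, ]
    fit <- trilaterate_unit(dataset$channel_positions, a, k_channels)
    data.frame(unit_id = id, x_um = fit$x_um, y_um = fit$y_um,
               degenerate = fit$degenerate)
  })
  do.call(rbind, rows)
}
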