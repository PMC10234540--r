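# Shared in-code fixtures for the test suite.

# A hand-built dataset: 10 trials 10 s apart; unit "a" fires 5 spikes in the
# post-stimulus response window of every trial and nothing else near events;
# unit "b" fires one spike per trial at exactly +12 ms.
fixture_deterministic_dataset <- function(n_trials = 10L) {
  ev <- seq(10, by = 10, length.out = n_trials)
  a <- unlist(lapply(ev, function(e) e + c(25, 30, 35, 40, 45) / 1000))
  b <- ev + 12 / 1000
  background <- seq(5, ev[n_trials] + 5, by = 2) + 0.3   # away from windows
  spike_dataset(
    data.frame(unit_id = rep(c("a", "b", "bg"),
                             c(length(a), length(b), length(background))),
               time_s = c(a, b, background)),
    events = data.frame(time_s = ev, label = "stim"))
}

# Two-column silicon-probe layout (16 sites, 20 um pitch).
fixture_probe <- function() {
  data.frame(channel = as.character(1:16),
             x_um = rep(c(0, 20), 8),
             y_um = rep(seq(0, 140, by = 20), each = 2))
}

# Noiseless amplitudes under the inverse-square decay model.
fixture_amplitudes <- function(probe, source, strength = 5e5) {
  d2 <- (probe$x_um - source[1])^2 + (probe$y_um - source[2])^2
  data.frame(channel = probe$channel, amp_uv = strength / d2)
}

# Success-indicator matrix with planted per-unit trial success probabilities.
fixture_success_matrix <- function(probs, n_trials = 40L, seed = 1L) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    m <- t(vapply(probs, function(p) runif(n_trials) < p, logical(n_trials)))
    rownames(m) <- sprintf("u%03d", seq_along(probs))
    m
  })
}

# Exact binomial 95% acceptance band for an observed proportion of p at n.
binom_band <- function(p, n, conf = 0.95) {
  a <- (1 - conf) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}

# Independent brute-force oracle for the exact binomial trial-count search:
# enumerates tail masses by summing dbinom terms and scans N upward.
oracle_trial_count <- function(p1, p0, power = 0.8, alpha = 0.05,
                               max_n = 2000L) {
  for (N in seq_len(max_n)) {
    k <- 0:N
    mass0 <- dbinom(k, N, p0)
    mass1 <- dbinom(k, N, p1)
    hi <- rev(cumsum(rev(mass0)))   # P(X >= k | p0)
    lo <- cumsum(mass0)             # P(X <= k | p0)
    region <- rep(FALSE, N + 1L)
    if (any(hi <= alpha / 2)) region[k >= min(k[hi <= alpha / 2])] <- TRUE
    if (any(lo <= alpha / 2)) region[k <= max(k[lo <= alpha / 2])] <- TRUE
    if (sum(mass1[region]) >= power) return(N)
  }
  NA_integer_
}
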