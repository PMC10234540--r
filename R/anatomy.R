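# Labeled-cell distribution statistics along the SC axes.

#' Soma coordinate table
#'
#' Validates a table of labeled cells: anterior-posterior position in mm
#' (bregma-relative, more negative = more caudal), depth and mediolateral
#' distance in micrometres, pathway label, semicolon-delimited markers
#' (e.g. `"RN;NeuN;GABA;iRN"`), brain and slice identifiers.
#'
#' @param cells data frame with columns `cell_id`, `ap_mm`, `dv_um`,
#'   `ml_um`, `pathway`, `markers`, `brain_id`, `slice_id`.
#' @param ap_range_mm permitted AP range, rostral first (default
#'   `c(-3.08, -4.28)`); cells outside it are allowed but flagged by the
#'   binning step.
#' @param dv_reference depth convention carried as an attribute
#'   (`"sc_dorsal_surface"` or `"pia"`).
#' @return the validated data frame with class `soma_table`.
#' @export
soma_table <- function(cells, ap_range_mm = c(-3.08, -4.28),
                       dv_reference = c("sc_dorsal_surface", "pia")) {
  dv_reference <- match.arg(dv_reference)
  need <- c("cell_id", "ap_mm", "dv_um", "ml_um", "pathway", "markers",
            "brain_id", "slice_id")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stopf("soma table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(cells)) {
    if (any(cells$dv_um < 0) || any(cells$ml_um < 0))
      stopf("dv_um and ml_um must be >= 0")
    if (any(!nzchar(cells$markers)))
      stopf("every cell must carry at least one marker")
  }
  structure(cells, class = c("soma_table", "data.frame"),
            ap_range_mm = ap_range_mm, dv_reference = dv_reference)
}

#' Test cells for a marker
#'
#' @param cells a [soma_table()] (or any data frame with a semicolon-joined
#'   `markers` column).
#' @param marker marker name, e.g. `"GABA"`.
#' @return logical vector.
#' @export
has_marker <- function(cells, marker) {
  vapply(strsplit(cells$markers, ";", fixed = TRUE),
         function(m) marker %in% m, logical(1))
}

#' Default rostro-caudal bin edges
#'
#' Thirteen 100-um bins covering the sampled SC sectioning positions -3.08
#' to -4.28 mm from bregma: each bin is centered on an atlas section
#' position (`from`, `from - width`, ..., `to`), so the edges run from
#' `from + width/2` to `to - width/2`, rostral to caudal (decreasing AP).
#'
#' @param from,to rostral and caudal section positions in mm.
#' @param width_mm bin width in mm (default 0.1).
#' @return decreasing numeric vector of bin edges (length `n_bins + 1`).
#' @export
ap_bin_edges <- function(from = -3.08, to = -4.28, width_mm = 0.1) {
  if (from <= to) stopf("rostral edge must be greater than caudal edge")
  seq(from + width_mm / 2, to - width_mm / 2, by = -width_mm)
}

#' Assign AP coordinates to rostro-caudal bins
#'
#' Bin `i` spans `[edges[i], edges[i+1])` going rostral to caudal (half-open
#' on the caudal side), with the final, most caudal bin closed. Values
#' outside the edges map to `NA`.
#'
#' @param ap numeric AP coordinates in mm (bregma-relative).
#' @param edges decreasing bin edges, e.g. from [ap_bin_edges()].
#' @return integer bin indices (`NA` for out-of-range values).
#' @export
ap_bin_index <- function(ap, edges) {
  x <- -ap
  e <- -edges                      # increasing
  idx <- findInterval(x, e, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(e) - 1L] <- NA_integer_
  idx
}

#' Bin labeled cells along the rostro-caudal axis
#'
#' Counts cells per 100-um AP bin and per brain. Bins are half-open on the
#' caudal side (a cell exactly at the rostral limit falls in the first bin)
#' with the final, most caudal bin closed. Cells outside the binned range
#' are reported separately, never silently dropped.
#'
#' @param cells a [soma_table()] or compatible data frame.
#' @param edges bin edges from [ap_bin_edges()] (rostral to caudal,
#'   decreasing).
#' @return object of class `binned_distribution`: list with `bin_edges_mm`,
#'   `counts` (brains x bins integer matrix), `normalized` (`NULL` until
#'   [normalize_per_brain()]), `out_of_range` (per-brain count),
#'   `quantiles` (per-brain and pooled median/Q1/Q3 of in-range AP values).
#' @export
bin_counts_along_ap <- function(cells, edges = ap_bin_edges()) {
  if (is.unsorted(-edges, strictly = TRUE)) stopf("edges must be strictly decreasing")
  nb <- length(edges) - 1L
  brains <- sort(unique(as.character(cells$brain_id)))
  if (length(brains) == 0L) brains <- "b1"
  counts <- matrix(0L, nrow = length(brains), ncol = nb,
                   dimnames = list(brains, NULL))
  oor <- setNames(integer(length(brains)), brains)
  qs <- list()
  if (nrow(cells)) {
    idx <- ap_bin_index(cells$ap_mm, edges)
    for (b in brains) {
      sel <- cells$brain_id == b
      tb <- tabulate(idx[sel], nbins = nb)
      counts[b, ] <- tb
      oor[b] <- sum(sel) - sum(tb)
      inr <- cells$ap_mm[sel & !is.na(idx)]
      if (length(inr))
        qs[[b]] <- quantile(inr, c(0.5, 0.25, 0.75), names = FALSE)
    }
  }
  pooled <- cells$ap_mm[!is.na(ap_bin_index(cells$ap_mm, edges))]
  quant <- data.frame(
    brain_id = c(names(qs), "pooled"),
    median_mm = c(vapply(qs, `[`, numeric(1), 1),
                  if (length(pooled)) median(pooled) else NA_real_),
    q1_mm = c(vapply(qs, `[`, numeric(1), 2),
              if (length(pooled)) quantile(pooled, 0.25, names = FALSE) else NA_real_),
    q3_mm = c(vapply(qs, `[`, numeric(1), 3),
              if (length(pooled)) quantile(pooled, 0.75, names = FALSE) else NA_real_),
    row.names = NULL)
  structure(list(bin_edges_mm = edges, counts = counts, normalized = NULL,
                 out_of_range = oor, quantiles = quant),
            class = "binned_distribution")
}

#' Normalize binned counts to each brain's maximum
#'
#' Divides every brain's bin counts by that brain's maximum count, so the
#' fullest bin equals 1; brains with no cells keep all-zero rows (with a
#' warning). Normalizing an already-normalized distribution is a no-op.
#'
#' @param dist a [bin_counts_along_ap()] result.
#' @return the distribution with its `normalized` matrix filled in.
#' @export
normalize_per_brain <- function(dist) {
  stopifnot(inherits(dist, "binned_distribution"))
  mx <- apply(dist$counts, 1, max)
  if (any(mx == 0 & rowSums(dist$counts) == 0) && any(mx == 0))
    warnf("brain(s) with no in-range cells left all-zero: %s",
          paste(rownames(dist$counts)[mx == 0], collapse = ", "))
  norm <- dist$counts / ifelse(mx == 0, 1, mx)
  dist$normalized <- norm
  dist
}

#' Nonparametric comparison battery for per-cell AP distributions
#'
#' For each group: one-sample Kolmogorov-Smirnov normality test of the
#' z-scored values against N(0, 1), plus median, quartiles and IQR. For two
#' groups: Wilcoxon rank-sum. For three or more: Kruskal-Wallis omnibus and
#' pairwise rank-sum tests with Bonferroni adjustment
#' (`p_adj = min(1, p * n_pairs)`). Groups with fewer than two values are
#' flagged and omitted from the tests.
#'
#' @param groups named list of numeric vectors (e.g. per-pathway AP values).
#' @return list with `summary` (per group: `n`, `median`, `q1`, `q3`,
#'   `iqr`, `ks_p`), `omnibus` (`method`, `p`), `pairwise` (data frame
#'   `group1`, `group2`, `p_raw`, `p_bonferroni`), `excluded` (names of
#'   omitted groups).
#' @export
compare_distributions <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  excluded <- names(groups)[sizes < 2L]
  summary_df <- data.frame(
    group = names(groups), n = as.integer(sizes),
    median = vapply(groups, function(x) if (length(x)) median(x) else NA_real_, 1),
    q1 = vapply(groups, function(x) if (length(x)) quantile(x, .25, names = FALSE) else NA_real_, 1),
    q3 = vapply(groups, function(x) if (length(x)) quantile(x, .75, names = FALSE) else NA_real_, 1),
    ks_p = vapply(groups, function(x) {
      if (length(x) < 3L || sd(x) == 0) return(NA_real_)
      suppressWarnings(ks.test((x - mean(x)) / sd(x), "pnorm")$p.value)
    }, 1),
    row.names = NULL)
  summary_df$iqr <- summary_df$q3 - summary_df$q1
  use <- groups[sizes >= 2L]
  if (length(use) < 2L) stopf("need at least 2 groups with >= 2 values each")
  omnibus <- if (length(use) == 2L) {
    list(method = "wilcoxon_rank_sum",
         p = suppressWarnings(wilcox.test(use[[1]], use[[2]])$p.value))
  } else {
    list(method = "kruskal_wallis", p = kruskal.test(use)$p.value)
  }
  pairs <- utils::combn(names(use), 2L)
  n_pairs <- ncol(pairs)
  p_raw <- vapply(seq_len(n_pairs), function(j) {
    suppressWarnings(wilcox.test(use[[pairs[1, j]]], use[[pairs[2, j]]])$p.value)
  }, numeric(1))
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         p_raw = p_raw,
                         p_bonferroni = pmin(1, p_raw * n_pairs),
                         row.names = NULL)
  list(summary = summary_df, omnibus = omnibus, pairwise = pairwise,
       excluded = excluded)
}

#' Proportion of a marker population with per-group breakdown
#'
#' Computes `100 * numerator / denominator` overall and per group (slice,
#' section or segment), with mean and SEM across groups. Inputs may be raw
#' counts or cell tables (rows are counted). Groups whose denominator falls
#' below `min_n` - typically from [min_slice_n_for_power()] - or equals zero
#' are excluded from the per-group statistics and listed with the reason.
#'
#' @param numerator count, or data frame of numerator cells.
#' @param denominator count, or data frame of denominator cells.
#' @param group_by grouping column name (present in both tables) for the
#'   per-group breakdown; ignored for count input.
#' @param digits rounding for the reported percent: 1 gives one-decimal
#'   percents, 0 nearest-integer percents.
#' @param min_n minimum per-group denominator (optional).
#' @return object of class `proportion_summary`: list with
#'   `numerator_count`, `denominator_count`, `percent`, `percent_rounded`,
#'   `per_group` (data frame `group`, `numerator`, `denominator`,
#'   `percent`), `mean_percent`, `sem_percent`, `excluded_groups`.
#' @examples
#' proportion_summary(84, 384)$percent_rounded        # 21.9
#' proportion_summary(41, 119, digits = 0)$percent_rounded  # 34
#' @export
proportion_summary <- function(numerator, denominator, group_by = NULL,
                               digits = 1, min_n = NULL) {
  per_group <- NULL
  if (is.data.frame(numerator) || is.data.frame(denominator)) {
    stopifnot(is.data.frame(numerator), is.data.frame(denominator))
    num <- nrow(numerator); den <- nrow(denominator)
    if (!is.null(group_by)) {
      gnum <- table(factor(numerator[[group_by]],
                           levels = sort(unique(denominator[[group_by]]))))
      gden <- table(factor(denominator[[group_by]]))
      per_group <- data.frame(group = names(gden),
                              numerator = as.integer(gnum[names(gden)]),
                              denominator = as.integer(gden), row.names = NULL)
    }
  } else {
    num <- numerator; den <- denominator
  }
  if (den <= 0) stopf("denominator must be positive")
  if (num > den) warnf("numerator exceeds denominator; not a subset proportion")
  excluded <- data.frame(group = character(0), reason = character(0))
  mean_pct <- sem_pct <- NA_real_
  if (!is.null(per_group)) {
    bad_zero <- per_group$denominator == 0
    bad_min <- !bad_zero & !is.null(min_n) & per_group$denominator < (min_n %||% 0)
    excluded <- data.frame(
      group = per_group$group[bad_zero | bad_min],
      reason = c(rep("zero_denominator", sum(bad_zero)),
                 rep("below_min_n", sum(bad_min))))
    per_group <- per_group[!(bad_zero | bad_min), , drop = FALSE]
    per_group$percent <- 100 * per_group$numerator / per_group$denominator
    if (nrow(per_group)) {
      mean_pct <- mean(per_group$percent)
      sem_pct <- sd(per_group$percent) / sqrt(nrow(per_group))
    }
  }
  structure(list(numerator_count = num, denominator_count = den,
                 percent = 100 * num / den,
                 percent_rounded = round(100 * num / den, digits),
                 per_group = per_group, mean_percent = mean_pct,
                 sem_percent = sem_pct, excluded_groups = excluded),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat(sprintf("%d / %d = %s%%\n", x$numerator_count, x$denominator_count,
              format(x$percent_rounded)))
  if (!is.null(x$per_group) && is.finite(x$mean_percent))
    cat(sprintf("per-group mean %.1f%% +/- %.1f%% SEM (%d groups)\n",
                x$mean_percent, x$sem_percent, nrow(x$per_group)))
  invisible(x)
}

#' Minimum per-slice sample size to resolve a proportion difference
#'
#' Smallest per-group count `n` at which a pooled two-proportion z-test
#' (two-sided `alpha`) detects the difference between `p1` and `p2` with the
#' target power, using the classical normal-approximation power formula.
#' Used to exclude marginal slices whose cell counts cannot support the
#' proportion comparison.
#'
#' @param p1,p2 the two proportions in (0, 1), `p1 != p2`.
#' @param power target power (default 0.8).
#' @param alpha two-sided significance level (default 0.05).
#' @param max_n search bound.
#' @return smallest integer `n` per group reaching the target power.
#' @export
min_slice_n_for_power <- function(p1, p2, power = 0.8, alpha = 0.05,
                                  max_n = 1e6) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) stopf("p1, p2 must lie in (0, 1)")
  if (p1 == p2) stopf("p1 must differ from p2")
  za <- qnorm(1 - alpha / 2)
  pbar <- (p1 + p2) / 2
  pow <- function(n) {
    se0 <- sqrt(2 * pbar * (1 - pbar) / n)
    se1 <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / n)
    pnorm((abs(p1 - p2) - za * se0) / se1)
  }
  n <- 2L
  while (n <= max_n && pow(n) < power) n <- n + 1L
  if (n > max_n) stopf("no n <= %g reaches power %.2f", max_n, power)
  n
}

#' Convergence statistics across input pairs
#'
#' Compares convergence neurons (CVG-RNs) across input pairs: (1) the mean
#' per-AP-bin CVG count of every pair, z-scored across the compared pairs
#' (mean 0, sd 1 over the set of pair means); (2) the fold difference
#' between two pair groups, computed on mean per-bin counts; (3) per-pair
#' CVG/RN proportions with median, mean and IQR over bins when per-bin RN
#' counts are supplied.
#'
#' @param cvg_counts pairs x bins matrix (or named list of per-bin vectors)
#'   of CVG-RN counts.
#' @param rn_counts named vector of total RN counts per pair, or a matrix of
#'   per-bin RN counts matching `cvg_counts`.
#' @param group_a,group_b pair names making up the two compared groups for
#'   the fold difference (e.g. cortex-cortex vs brainstem-cortex); defaults
#'   to first pair vs the rest.
#' @return object of class `convergence_stats`: list with `pair_means`,
#'   `z` (named z-scores, mean 0 sd 1), `fold_difference`, `proportions`
#'   (per pair: `cvg`, `rn`, `proportion`, and per-bin `median`, `mean`,
#'   `iqr` when available).
#' @export
convergence_stats <- function(cvg_counts, rn_counts = NULL,
                              group_a = NULL, group_b = NULL) {
  if (is.list(cvg_counts) && !is.data.frame(cvg_counts))
    cvg_counts <- do.call(rbind, cvg_counts)
  stopifnot(is.matrix(cvg_counts))
  pairs <- rownames(cvg_counts) %||% paste0("pair", seq_len(nrow(cvg_counts)))
  rownames(cvg_counts) <- pairs
  if (nrow(cvg_counts) < 2L) stopf("need >= 2 input pairs")
  m <- rowMeans(cvg_counts)
  s <- sd(m)
  z <- if (s == 0) { warnf("identical pair means; z-scores set to 0"); m * 0 }
       else (m - mean(m)) / s
  if (is.null(group_a)) group_a <- pairs[1]
  if (is.null(group_b)) group_b <- setdiff(pairs, group_a)
  mean_a <- mean(cvg_counts[group_a, , drop = FALSE])
  mean_b <- mean(cvg_counts[group_b, , drop = FALSE])
  fold <- if (mean_b == 0) { warnf("group B mean is 0; fold undefined"); NA_real_ }
          else mean_a / mean_b
  proportions <- NULL
  if (!is.null(rn_counts)) {
    if (is.matrix(rn_counts)) {
      per_bin <- cvg_counts / ifelse(rn_counts == 0, NA, rn_counts)
      proportions <- data.frame(
        pair = pairs,
        cvg = rowSums(cvg_counts), rn = rowSums(rn_counts),
        proportion = rowSums(cvg_counts) / rowSums(rn_counts),
        median = apply(per_bin, 1, median, na.rm = TRUE),
        mean = rowMeans(per_bin, na.rm = TRUE),
        iqr = apply(per_bin, 1, function(x)
          diff(quantile(x, c(.25, .75), na.rm = TRUE, names = FALSE))),
        row.names = NULL)
    } else {
      proportions <- data.frame(
        pair = pairs, cvg = rowSums(cvg_counts),
        rn = as.numeric(rn_counts[pairs]),
        proportion = rowSums(cvg_counts) / as.numeric(rn_counts[pairs]),
        row.names = NULL)
    }
  }
  structure(list(pair_means = m, z = z, fold_difference = fold,
                 group_a = group_a, group_b = group_b,
                 proportions = proportions),
            class = "convergence_stats")
}
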