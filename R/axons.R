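# Axon-projection output maps: AP-bin x nucleus count matrices, relative
# axon counts (RAC) and per-nucleus z-scored projection strengths.

.dien_nuclei <- c("PO", "VM", "PF", "ZI", "LP", "APT", "ETH", "LD", "MD",
                  "PC", "PRC", "PV", "Re", "RH", "STH")
.bs_nuclei <- c("7N", "Gi", "PnC", "PnO", "IRt", "Sp5", "PCRt")

#' Target-nucleus lists and AP ranges per region
#'
#' Fifteen diencephalic and seven brainstem target nuclei are scored;
#' axonal signal is considered in the AP ranges -1.22 to -2.54 mm
#' (diencephalon) and -5.4 to -6.4 mm (brainstem).
#'
#' @param region `"diencephalon"` or `"brainstem"`.
#' @return character vector of nucleus abbreviations.
#' @export
sc_target_nuclei <- function(region = c("diencephalon", "brainstem")) {
  region <- match.arg(region)
  if (region == "diencephalon") .dien_nuclei else .bs_nuclei
}

region_ap_range <- function(region) {
  switch(region, diencephalon = c(-1.22, -2.54), brainstem = c(-5.4, -6.4),
         stopf("unknown region %s", region))
}

#' Axon-count matrix container
#'
#' @param counts non-negative integer matrix, AP bins (rows, rostral to
#'   caudal) x nuclei (columns); column names must match the region's
#'   nucleus list.
#' @param region `"diencephalon"` (15 nuclei) or `"brainstem"` (7 nuclei).
#' @param pathway pathway label, e.g. `"MC-RN"`.
#' @param n_ap_bins number of 100-um AP bins (defaults to `nrow(counts)`).
#' @param ap_bin_edges optional explicit bin edges (rostral to caudal).
#' @return object of class `axon_count_matrix`.
#' @export
axon_count_matrix <- function(counts, region, pathway = "RN",
                              n_ap_bins = nrow(counts), ap_bin_edges = NULL) {
  nuclei <- sc_target_nuclei(region)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    if (ncol(counts) != length(nuclei))
      stopf("expected %d nucleus columns for %s, got %d",
            length(nuclei), region, ncol(counts))
    colnames(counts) <- nuclei
  }
  bad <- setdiff(colnames(counts), nuclei)
  if (length(bad)) stopf("unknown nucleus label(s) for %s: %s", region,
                         paste(bad, collapse = ", "))
  counts <- counts[, nuclei[nuclei %in% colnames(counts)], drop = FALSE]
  if (ncol(counts) != length(nuclei))
    stopf("matrix must cover all %d %s nuclei", length(nuclei), region)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers")
  if (is.null(ap_bin_edges)) {
    rng <- region_ap_range(region)
    ap_bin_edges <- seq(rng[1], rng[2], length.out = n_ap_bins + 1L)
  }
  structure(list(counts = counts, region = region, pathway = pathway,
                 ap_bin_edges = ap_bin_edges),
            class = "axon_count_matrix")
}

#' @export
print.axon_count_matrix <- function(x, ...) {
  cat(sprintf("<axon_count_matrix> %s / %s: %d bins x %d nuclei, %d axons\n",
              x$pathway, x$region, nrow(x$counts), ncol(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' Build an axon-count matrix from per-slice nucleus counts
#'
#' Bins per-slice counts into 100-um AP bins over the region's AP range and
#' accumulates them per nucleus. Nucleus labels outside the region's fixed
#' list are rejected by name; slices outside the AP range are rejected.
#'
#' @param slices data frame with columns `ap_mm`, `nucleus`, `count`.
#' @param region `"diencephalon"` or `"brainstem"`.
#' @param pathway pathway label carried on the output.
#' @param n_ap_bins number of AP bins (default: as many full 100-um bins as
#'   fit the region range).
#' @return an [axon_count_matrix()].
#' @export
build_axon_matrix <- function(slices, region, pathway = "RN",
                              n_ap_bins = NULL) {
  stopifnot(all(c("ap_mm", "nucleus", "count") %in% names(slices)))
  nuclei <- sc_target_nuclei(region)
  rng <- region_ap_range(region)
  if (is.null(n_ap_bins))
    n_ap_bins <- if (region == "diencephalon") 13L else 10L
  edges <- seq(rng[1], rng[2], length.out = n_ap_bins + 1L)
  bad <- setdiff(unique(slices$nucleus), nuclei)
  if (length(bad))
    stopf("nucleus label(s) not in the %s list: %s", region,
          paste(bad, collapse = ", "))
  counts <- matrix(0L, nrow = n_ap_bins, ncol = length(nuclei),
                   dimnames = list(NULL, nuclei))
  if (nrow(slices)) {
    idx <- ap_bin_index(slices$ap_mm, edges)
    if (any(is.na(idx)))
      stopf("slice AP coordinate(s) outside the %s range [%g, %g] mm",
            region, rng[2], rng[1])
    for (r in seq_len(nrow(slices)))
      counts[idx[r], slices$nucleus[r]] <-
        counts[idx[r], slices$nucleus[r]] + as.integer(slices$count[r])
  }
  axon_count_matrix(counts, region = region, pathway = pathway,
                    n_ap_bins = n_ap_bins, ap_bin_edges = edges)
}

#' Relative axon counts
#'
#' `RAC = counts / max(counts)`: every entry of the pathway's count matrix
#' divided by the matrix's global maximum, giving values in `[0, 1]` that
#' are invariant to scaling all counts by a positive constant. An all-zero
#' matrix yields all-zero RACs with a warning.
#'
#' @param mat an [axon_count_matrix()] or a plain count matrix.
#' @return numeric matrix of the same shape.
#' @export
relative_axon_count <- function(mat) {
  counts <- if (inherits(mat, "axon_count_matrix")) mat$counts else as.matrix(mat)
  mx <- max(counts)
  if (mx == 0) {
    warnf("all counts are zero; RAC set to zero")
    return(counts * 0)
  }
  counts / mx
}

#' Per-nucleus z-scored projection strengths
#'
#' Sums counts per nucleus across the AP dimension and z-scores the totals
#' across nuclei (mean 0, sd 1; sample standard deviation by default). For
#' the bar-plot normalization both readings of "normalized to the pathway
#' maximum" are emitted: the z-scores divided by the maximum absolute
#' z-score, and the raw totals divided by the maximum total.
#'
#' @param mat an [axon_count_matrix()] or plain count matrix (bins x
#'   nuclei).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return list with `totals`, `z`, `z_maxnorm` (z / max |z|),
#'   `totals_maxnorm` (totals / max total); all named by nucleus.
#' @export
nucleus_zscores <- function(mat, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  counts <- if (inherits(mat, "axon_count_matrix")) mat$counts else as.matrix(mat)
  if (ncol(counts) < 2L) stopf("need at least 2 nuclei")
  totals <- colSums(counts)
  s <- sd(totals)
  if (sd_type == "population")
    s <- s * sqrt((length(totals) - 1) / length(totals))
  if (is.na(s) || s == 0) {
    warnf("zero variance across nuclei; z-scores set to 0")
    z <- totals * 0
  } else {
    z <- (totals - mean(totals)) / s
  }
  mz <- max(abs(z))
  mt <- max(totals)
  list(totals = totals, z = z,
       z_maxnorm = if (mz > 0) z / mz else z,
       totals_maxnorm = if (mt > 0) totals / mt else totals)
}
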