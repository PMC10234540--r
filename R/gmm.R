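# Two-component Gaussian mixture for convergence-zone localization.
#
# A small, purpose-built EM for full-covariance bivariate mixtures: the
# per-iteration log-likelihood trace, the restart scheme and the density-mode
# search are part of the analysis contract, so the fit is implemented here
# rather than delegated (an external mixture fitter serves as an independent
# cross-check in the test suite).

log_dmvnorm2 <- function(x, mu, sigma) {
  L <- chol(sigma)
  d <- sweep(x, 2L, mu)
  z <- backsolve(L, t(d), transpose = TRUE)
  -log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

# k-means++-style seeding: first center uniform, each further center drawn
# with probability proportional to squared distance from the nearest chosen.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(x, 1L, function(p) min(colSums((t(centers) - p)^2)))
    if (all(d2 == 0)) {
      centers <- rbind(centers, x[sample.int(n, 1L), , drop = FALSE])
    } else {
      centers <- rbind(centers, x[sample.int(n, 1L, prob = d2), , drop = FALSE])
    }
  }
  centers
}

em_gmm_once <- function(x, k, max_iter, tol, reg) {
  n <- nrow(x)
  centers <- kmeanspp_centers(x, k)
  assign <- apply(x, 1L, function(p) which.min(colSums((t(centers) - p)^2)))
  w <- pmax(tabulate(assign, k), 1) / n
  w <- w / sum(w)
  mu <- lapply(seq_len(k), function(j) {
    if (any(assign == j)) colMeans(x[assign == j, , drop = FALSE]) else centers[j, ]
  })
  floored <- FALSE
  sig <- lapply(seq_len(k), function(j) {
    xs <- x[assign == j, , drop = FALSE]
    S <- if (nrow(xs) > 2L) stats::cov(xs) else stats::cov(x)
    regularize_cov(S, reg, x)
  })
  floored <- any(vapply(sig, function(S) isTRUE(attr(S, "floored")), logical(1)))
  ll_trace <- numeric(0)
  ll_old <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j)
      log(w[j]) + log_dmvnorm2(x, mu[[j]], sig[[j]]), numeric(n))
    mx <- apply(logp, 1L, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logp - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    nk <- colSums(resp)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[[j]] <- colSums(x * resp[, j]) / nk[j]
      d <- sweep(x, 2L, mu[[j]])
      S <- crossprod(d * sqrt(resp[, j])) / nk[j]
      sig[[j]] <- regularize_cov(S, reg, x)
      if (isTRUE(attr(sig[[j]], "floored"))) floored <- TRUE
    }
  }
  list(weights = w, means = mu, covariances = sig, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, responsibilities = resp, floored = floored)
}

# Floors near-singular covariances (eigenvalues below a small fraction of
# the data variance); flags the result so the caller can warn once per fit.
regularize_cov <- function(S, reg, x) {
  floor_val <- reg * max(apply(x, 2L, var), .Machine$double.eps)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < floor_val) {
    S <- S + diag(floor_val, ncol(S))
    attr(S, "floored") <- TRUE
  }
  S
}

#' Mixture density of a fitted two-component GMM
#'
#' @param fit a [fit_convergence_gmm()] result.
#' @param x two-column matrix of (DV, ML) points in micrometres.
#' @return numeric vector of mixture densities.
#' @export
gmm_density <- function(fit, x) {
  x <- as.matrix(x)
  dens <- 0
  for (j in seq_along(fit$weights))
    dens <- dens + fit$weights[j] *
      exp(log_dmvnorm2(x, fit$means[[j]], fit$covariances[[j]]))
  dens
}

#' Localize a convergence zone with a two-component Gaussian mixture
#'
#' Fits a full-covariance Gaussian mixture to the depth x mediolateral
#' coordinates of convergence neurons by expectation-maximization
#' (k-means++-style seeding, best of `n_init` restarts, convergence when the
#' log-likelihood improves by less than `tol`). The location of highest
#' probability - the convergence-zone peak - is found by evaluating the
#' mixture density on a `grid_n` x `grid_n` grid over the data bounding box
#' and refining the best grid point by Nelder-Mead ascent.
#'
#' Degenerate point sets (collinear or duplicated) are handled by flooring
#' the covariance eigenvalues, with a warning.
#'
#' @param points two-column matrix or data frame of (DV, ML) coordinates in
#'   micrometres; at least 10 points.
#' @param n_components number of mixture components (default 2).
#' @param seed integer seed controlling the restarts.
#' @param n_init number of EM restarts (default 10).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param reg relative covariance eigenvalue floor, as a fraction of the
#'   data variance; guards against spiky single-point components
#'   (default 1e-3).
#' @param grid_n density-grid resolution per axis for the mode search.
#' @return object of class `gmm_zone`: list with `weights`, `means`,
#'   `covariances`, `loglik`, `loglik_trace` (best restart), `mode`
#'   (named `dv_um`, `ml_um`), `n_points`, `seed`.
#' @export
fit_convergence_gmm <- function(points, n_components = 2L, seed = 1L,
                                n_init = 10L, max_iter = 500L, tol = 1e-6,
                                reg = 1e-3, grid_n = 200L) {
  x <- as.matrix(points)
  if (ncol(x) != 2L) stopf("points must have two columns (DV, ML)")
  if (nrow(x) < 10L) stopf("need at least 10 points")
  storage.mode(x) <- "double"
  # Collapsed components (covariance at the regularization floor) win on
  # inflated likelihood; prefer non-collapsed restarts, falling back to a
  # floored solution only when every restart needed the floor (e.g. truly
  # collinear data).
  best <- NULL
  best_floored <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- em_gmm_once(x, n_components, max_iter, tol, reg)
      if (fit$floored) {
        if (is.null(best_floored) || fit$loglik > best_floored$loglik)
          best_floored <- fit
      } else if (is.null(best) || fit$loglik > best$loglik) {
        best <- fit
      }
    }
  })
  if (is.null(best)) best <- best_floored
  if (isTRUE(best$floored))
    warnf("degenerate covariance regularized (diagonal floor added)")
  mode <- gmm_mode(best, x, grid_n)
  structure(list(weights = best$weights, means = best$means,
                 covariances = best$covariances, loglik = best$loglik,
                 loglik_trace = best$loglik_trace, mode = mode,
                 n_points = nrow(x), seed = as.integer(seed)),
            class = "gmm_zone")
}

gmm_mode <- function(fit, x, grid_n) {
  rng1 <- range(x[, 1]); rng2 <- range(x[, 2])
  g1 <- seq(rng1[1], rng1[2], length.out = grid_n)
  g2 <- seq(rng2[1], rng2[2], length.out = grid_n)
  grid <- cbind(rep(g1, times = grid_n), rep(g2, each = grid_n))
  dens <- gmm_density(fit, grid)
  start <- grid[which.max(dens), ]
  # include component means as candidate starts; the global mode is near one
  cand <- rbind(start, do.call(rbind, fit$means))
  refined <- t(apply(cand, 1L, function(p)
    optim(p, function(q) -gmm_density(fit, matrix(q, 1L)),
          method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14))$par))
  vals <- gmm_density(fit, refined)
  best <- refined[which.max(vals), ]
  c(dv_um = unname(best[1]), ml_um = unname(best[2]))
}

#' @export
print.gmm_zone <- function(x, ...) {
  cat(sprintf("<gmm_zone> %d components, n = %d, loglik = %.2f\n",
              length(x$weights), x$n_points, x$loglik))
  for (j in seq_along(x$weights))
    cat(sprintf("  comp %d: w = %.3f, mean = (%.0f, %.0f) um\n", j,
                x$weights[j], x$means[[j]][1], x$means[[j]][2]))
  cat(sprintf("  mode: (%.0f, %.0f) um [DV, ML]\n", x$mode[1], x$mode[2]))
  invisible(x)
}
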