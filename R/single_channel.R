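## Unitary MET current estimation from 100 kHz sweeps: amplitude-histogram
## dual-Gaussian ("dual-peak") fitting by expectation-maximization.

# k-component Gaussian mixture EM on raw samples; returns means, sds,
# weights and log-likelihood. Deterministic given the initial means.
em_gauss <- function(x, mu0, sigma0 = NULL, max_iter = 500, tol = 1e-8) {
  k <- length(mu0)
  n <- length(x)
  mu <- mu0
  sigma <- if (is.null(sigma0)) rep(stats::sd(x) / k, k) else sigma0
  sigma <- pmax(sigma, 1e-3)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(vapply(seq_len(k), function(j)
      sum(resp[, j] * (x - mu[j])^2) / nk[j], 0))
    sigma <- pmax(sigma, 1e-3)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll, iter = it,
       bic = -2 * ll + (3 * k - 1) * log(n))
}

#' Fit a two-component Gaussian mixture to amplitude samples
#'
#' The dual-peak fit behind unitary-current estimation: raw samples (not
#' binned counts) are fitted by expectation-maximization with
#' quantile-based initial means plus seeded random restarts, and the
#' component with the more negative mean is labelled "open" (inward
#' current at -70 mV). The unitary current is the difference of the two
#' means, which makes the estimate invariant to any constant offset of the
#' samples.
#'
#' @param samples numeric vector of amplitudes (pA); at least 1000.
#' @param n_restarts number of seeded random restarts beyond the quantile
#'   initialization.
#' @param seed RNG seed for the restarts.
#' @param min_separation components closer than this (pA) are considered
#'   collapsed and rejected as degenerate.
#' @return An object of class `hc_mixfit`: `mu_closed`, `mu_open`,
#'   `sigma_closed`, `sigma_open`, `w_open`, `i_unit` (= mu_open -
#'   mu_closed, < 0), `loglik`, `bic`.
#' @export
fit_two_gaussians <- function(samples, n_restarts = 5L, seed = 1L,
                              min_separation = 0.5) {
  x <- as.numeric(samples)
  if (length(x) < 1000)
    stop("need at least 1000 samples for a stable dual-peak fit")
  set.seed(seed)
  inits <- list(stats::quantile(x, c(0.9, 0.1)),
                stats::quantile(x, c(0.75, 0.25)))
  for (r in seq_len(n_restarts))
    inits <- c(inits, list(sort(stats::runif(2, min(x), max(x)),
                                decreasing = TRUE)))
  best <- NULL
  for (mu0 in inits) {
    f <- em_gauss(x, as.numeric(mu0))
    if (is.null(best) || f$loglik > best$loglik) best <- f
  }
  o <- order(best$mu, decreasing = TRUE)   # closed (near 0) first
  mu <- best$mu[o]; sg <- best$sigma[o]; w <- best$w[o]
  if (abs(mu[1] - mu[2]) < min_separation)
    stop(sprintf(
      "degenerate fit: components collapse within %.2g pA (means %.3g, %.3g)",
      min_separation, mu[1], mu[2]))
  if (min(w) < 0.02)
    stop(sprintf(
      "degenerate fit: component weight %.2g vanishes (unimodal input?)",
      min(w)))
  structure(list(mu_closed = mu[1], mu_open = mu[2],
                 sigma_closed = sg[1], sigma_open = sg[2],
                 w_open = w[2], i_unit = mu[2] - mu[1],
                 loglik = best$loglik, bic = best$bic),
            class = "hc_mixfit")
}

#' @export
print.hc_mixfit <- function(x, ...) {
  cat(sprintf(paste0("<hc_mixfit> i_unit = %.3g pA ",
                     "(closed %.3g +/- %.2g, open %.3g +/- %.2g, ",
                     "w_open = %.3g)\n"),
              x$i_unit, x$mu_closed, x$sigma_closed, x$mu_open,
              x$sigma_open, x$w_open))
  invisible(x)
}

# samples of one sweep inside the probe-step window
step_samples <- function(tr, window) {
  tt <- trace_times(tr)
  tr$samples[tt >= window[1] & tt < window[2]]
}

#' Select sweeps with obvious single-channel events
#'
#' Operationalizes "traces with obvious single-channel events": a sweep is
#' retained when (i) its peak inward excursion from the pre-step baseline
#' exceeds `k` times the baseline noise rms, and (ii) its step-window
#' samples occupy both levels (the fraction beyond the half-excursion
#' midpoint lies within `occ_range` -- a bimodality screen), and
#' optionally (iii) a three-component mixture does not beat the
#' two-component fit by more than `bic_margin` (sweeps with double
#' openings are excluded). Selection is deterministic given the data.
#'
#' @param rec a sweep recording from [simulate_single_channel()] (or the
#'   same layout: pA sweep traces plus a `probe_step` stimulus epoch).
#' @param k excursion threshold in baseline-rms units (default 4).
#' @param occ_range admissible open-level occupancy range.
#' @param screen_multilevel run the 3-vs-2-component screen.
#' @param bic_margin BIC margin for the multilevel exclusion.
#' @return the input recording containing only the retained sweeps, with
#'   attribute `retained_idx`; errors if nothing survives.
#' @export
select_event_sweeps <- function(rec, k = 4, occ_range = c(0.05, 0.95),
                                screen_multilevel = TRUE, bic_margin = 10) {
  stopifnot(inherits(rec, "hc_recording"))
  stim <- Filter(function(e) e$track == "stimulus" &&
                   startsWith(e$label, "probe_step"), rec$epochs)
  if (!length(stim)) stop("no probe_step stimulus epoch in this recording")
  win <- c(stim[[1]]$t_start, stim[[1]]$t_end)
  keep <- logical(length(rec$traces))
  for (si in seq_along(rec$traces)) {
    tr <- rec$traces[[si]]
    tt <- trace_times(tr)
    pre <- tr$samples[tt < win[1]]
    stepx <- step_samples(tr, win)
    if (length(pre) < 10 || length(stepx) < 10) next
    base <- stats::median(pre)
    rms <- stats::sd(pre)
    if (!is.finite(rms) || rms <= 0) rms <- 1e-6
    # excursion read from the display-filtered sweep: gating dwells are
    # long against the kernel, so event amplitudes survive while noise
    # extremes (which scale with sample count) are suppressed
    smx <- if (length(tr$samples) >= 3)
      step_samples(binomial_smooth(tr, 20), win) else stepx
    exc <- base - min(smx)            # inward excursion, positive
    if (exc < k * rms) next
    mid <- base - exc / 2
    occ <- mean(smx < mid)
    if (occ < occ_range[1] || occ > occ_range[2]) next
    keep[si] <- TRUE
    if (screen_multilevel && length(stepx) >= 1000) {
      f2 <- em_gauss(stepx, as.numeric(stats::quantile(stepx, c(0.9, 0.1))))
      f3 <- em_gauss(stepx, as.numeric(stats::quantile(stepx,
                                                       c(0.9, 0.5, 0.1))))
      if (f3$bic < f2$bic - bic_margin) keep[si] <- FALSE
    }
  }
  if (!any(keep))
    stop(paste("no sweeps retained; review the excursion threshold k",
               "or the occupancy range"))
  out <- rec
  out$traces <- rec$traces[keep]
  attributes(out) <- c(attributes(out)[setdiff(names(attributes(out)),
                                               "retained_idx")],
                       list(retained_idx = which(keep)))
  out
}

#' Unitary current of a sweep recording
#'
#' Convenience pipeline: select event sweeps, pool their step-window
#' samples and run the dual-peak fit.
#'
#' @inheritParams select_event_sweeps
#' @param seed RNG seed for the EM restarts.
#' @param ... passed to [select_event_sweeps()].
#' @return An `hc_mixfit`.
#' @export
unitary_from_recording <- function(rec, seed = 1L, ...) {
  sel <- select_event_sweeps(rec, ...)
  stim <- Filter(function(e) e$track == "stimulus" &&
                   startsWith(e$label, "probe_step"), sel$epochs)
  win <- c(stim[[1]]$t_start, stim[[1]]$t_end)
  pooled <- unlist(lapply(sel$traces, step_samples, window = win),
                   use.names = FALSE)
  fit_two_gaussians(pooled, seed = seed)
}

#' Summarize unitary currents by position and Ca2+ regime
#'
#' Group means +/- SEM of fitted unitary currents across cells, per
#' (cochlear position, Ca2+ regime) group. Single-member groups report
#' SEM 0 and are flagged.
#'
#' @param fits data.frame with columns `position`, `ca_mM` and `i_unit`
#'   (one row per cell or per fit).
#' @return data.frame with `position`, `ca_mM`, `n`, `mean_i_unit`,
#'   `sem_i_unit`, `single_n` flag.
#' @export
summarize_unitary <- function(fits) {
  stopifnot(all(c("position", "ca_mM", "i_unit") %in% names(fits)))
  key <- interaction(fits$position, fits$ca_mM, drop = TRUE)
  out <- do.call(rbind, lapply(split(fits, key), function(d)
    data.frame(position = d$position[1], ca_mM = d$ca_mM[1],
               n = nrow(d), mean_i_unit = mean(d$i_unit),
               sem_i_unit = if (nrow(d) > 1)
                 stats::sd(d$i_unit) / sqrt(nrow(d)) else 0,
               single_n = nrow(d) == 1L)))
  rownames(out) <- NULL
  out[order(out$ca_mM, out$position), , drop = FALSE]
}
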