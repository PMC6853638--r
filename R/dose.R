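#' Hill dose-inhibition parameters
#'
#' Parameterizes the Hill equation `I_X / I_max = X^h / (K^h + X^h)`, where
#' `K` is the half-inhibition dose (IC50) and `h` the Hill slope. For
#' inhibition curves `h` is negative, so the normalized current decreases
#' monotonically from 1 (no blocker) towards 0 and equals 1/2 at `X = K`.
#'
#' @param K IC50, in the units of the dose axis (uM for drug blockers,
#'   mM for Ca2+ series). Must be > 0.
#' @param h Hill slope (dimensionless, non-zero; negative for inhibition).
#' @param I_max current in the control condition (pA); defaults to 1 for
#'   normalized curves.
#' @return An object of class `hc_hillparams`.
#' @export
hill_params <- function(K, h, I_max = 1) {
  if (!is.finite(K) || K <= 0) stop("K (IC50) must be > 0")
  if (!is.finite(h) || h == 0) stop("Hill slope h must be non-zero")
  if (!is.finite(I_max)) stop("I_max must be finite")
  structure(list(K = K, h = h, I_max = I_max), class = "hc_hillparams")
}

#' @export
print.hc_hillparams <- function(x, ...) {
  cat(sprintf("<hc_hillparams> K = %g, h = %g, I_max = %g\n",
              x$K, x$h, x$I_max))
  invisible(x)
}

#' Evaluate the Hill dose-inhibition equation
#'
#' Returns `X^h / (K^h + X^h)` as a fraction of `I_max`. Computed as
#' `1 / (1 + (K/X)^h)` for numerical stability at extreme doses. `X = 0` is
#' handled by the analytic limit (1 for `h < 0`, 0 for `h > 0`).
#'
#' @param params an [hill_params()].
#' @param X dose vector (>= 0), same units as `params$K`.
#' @return numeric vector of normalized responses in `[0, 1]`.
#' @export
hill_eval <- function(params, X) {
  stopifnot(inherits(params, "hc_hillparams"))
  if (any(X < 0)) stop("dose X must be >= 0")
  out <- numeric(length(X))
  zero <- X == 0
  out[zero] <- if (params$h < 0) 1 else 0
  out[!zero] <- 1 / (1 + (params$K / X[!zero])^params$h)
  out
}

#' Simulate a dose-inhibition table
#'
#' Generates normalized dose-response points from a known Hill curve with
#' multiplicative Gaussian noise, one row per (cell, dose): the synthetic
#' ground truth for fitter validation and parameter-recovery studies.
#'
#' @param params true [hill_params()].
#' @param doses dose vector (typically log-spaced over the experimental
#'   range).
#' @param n_cells number of simulated cells.
#' @param cv multiplicative noise coefficient of variation (default 0.05).
#' @param seed RNG seed.
#' @param column name for the response column (`"I_MET"` or `"I_BG"`).
#' @return data.frame with columns `cell_id`, `dose`, and the response
#'   column (normalized to the control level).
#' @export
simulate_dose_table <- function(params, doses, n_cells = 8, cv = 0.05,
                                seed = 1L, column = "I_MET") {
  stopifnot(inherits(params, "hc_hillparams"))
  set.seed(seed)
  mu <- hill_eval(params, doses)
  tab <- do.call(rbind, lapply(seq_len(n_cells), function(ci) {
    y <- mu * (1 + stats::rnorm(length(doses), 0, cv))
    data.frame(cell_id = ci, dose = doses, y = y)
  }))
  names(tab)[names(tab) == "y"] <- column
  tab
}

# normalize responses to the within-cell zero-dose control, dropping the
# zero-dose rows afterwards; tables without a zero dose are assumed to be
# pre-normalized
normalize_dose_table <- function(tab, column) {
  if (!all(c("dose", column) %in% names(tab)))
    stop("dose table must have columns 'dose' and '", column, "'")
  if (is.null(tab$cell_id)) tab$cell_id <- 1L
  if (any(tab$dose == 0)) {
    sp <- split(tab, tab$cell_id)
    tab <- do.call(rbind, lapply(sp, function(d) {
      ctrl <- mean(d[[column]][d$dose == 0])
      if (!is.finite(ctrl) || ctrl == 0)
        stop("zero or undefined control response for cell ", d$cell_id[1])
      d[[column]] <- d[[column]] / ctrl
      d[d$dose > 0, , drop = FALSE]
    }))
    rownames(tab) <- NULL
  }
  tab
}

#' Fit the Hill equation to a dose-inhibition table
#'
#' Least-squares fit of [hill_eval()] to normalized responses, optimized on
#' `log K` to enforce positivity, with the Hill slope unconstrained but
#' initialized negative (inhibition). If the table contains zero-dose rows,
#' responses are first normalized to the within-cell zero-dose control;
#' otherwise they are taken as already normalized. Confidence intervals are
#' percentile bootstrap over cells (replicates within a cell are correlated,
#' so cells, not points, are resampled).
#'
#' @param tab data.frame with columns `dose`, `cell_id` (optional) and the
#'   response column. At least 4 distinct positive doses are required.
#' @param column response column to fit, e.g. `"I_MET"` or `"I_BG"`.
#' @param init optional [hill_params()] starting values; by default `K`
#'   starts at the dose whose mean response is nearest 0.5 and `h` at -1.
#' @param n_boot bootstrap resamples (0 to skip CIs).
#' @param seed RNG seed for the bootstrap.
#' @param plateau if `TRUE`, fit a residual plateau `p` so that the model is
#'   `p + (1 - p) * hill`; used for responses that saturate above zero
#'   (e.g. the MET current under Ca2+ substitution).
#' @return An object of class `hc_hillfit`: list with `params`
#'   ([hill_params()]), `plateau`, `ci` (2.5/97.5 percentiles for K, h and
#'   plateau if fitted), `residuals` and `n_boot`.
#' @export
fit_hill <- function(tab, column = "I_MET", init = NULL, n_boot = 500L,
                     seed = 1L, plateau = FALSE) {
  tab <- normalize_dose_table(tab, column)
  x <- tab$dose
  y <- tab[[column]]
  if (length(unique(x)) < 4L)
    stop("Hill fitting needs at least 4 distinct doses")
  if (length(unique(signif(y, 10))) == 1L)
    stop("all responses are equal; no dose dependence to fit")
  fit1 <- function(x, y, start) {
    df <- data.frame(x = x, y = y)
    if (plateau) {
      minpack.lm::nlsLM(
        y ~ p + (1 - p) / (1 + (exp(lK) / x)^h), data = df,
        start = c(start, list(p = 0.1)),
        lower = c(lK = log(min(x) / 100), h = -20, p = 0),
        upper = c(lK = log(max(x) * 100), h = 20, p = 0.95),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ 1 / (1 + (exp(lK) / x)^h), data = df, start = start,
        lower = c(lK = log(min(x) / 100), h = -20),
        upper = c(lK = log(max(x) * 100), h = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  if (is.null(init)) {
    mu <- tapply(y, x, mean)
    K0 <- as.numeric(names(mu))[which.min(abs(mu - 0.5))]
    starts <- list(list(lK = log(K0), h = -1))
    # fallback grid in case the half-maximal guess is poor
    for (K0b in stats::quantile(unique(x), c(0.25, 0.75)))
      starts <- c(starts, list(list(lK = log(as.numeric(K0b)), h = -1)))
  } else {
    stopifnot(inherits(init, "hc_hillparams"))
    starts <- list(list(lK = log(init$K), h = init$h))
  }
  fit <- NULL; tried <- character()
  for (st in starts) {
    fit <- tryCatch(fit1(x, y, st), error = function(e) NULL)
    tried <- c(tried, sprintf("lK=%.3g,h=%.3g", st$lK, st$h))
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Hill fit did not converge; initializations tried: ",
         paste(tried, collapse = "; "))
  cf <- stats::coef(fit)
  boot <- NULL
  if (n_boot > 0L) {
    set.seed(seed)
    cells <- unique(tab$cell_id)
    sp <- split(tab, tab$cell_id)
    boot <- t(vapply(seq_len(n_boot), function(b) {
      pick <- sample(as.character(cells), length(cells), replace = TRUE)
      bt <- do.call(rbind, sp[pick])
      bf <- tryCatch(fit1(bt$dose, bt[[column]],
                          list(lK = cf[["lK"]], h = cf[["h"]])),
                     error = function(e) NULL)
      if (is.null(bf)) return(c(K = NA_real_, h = NA_real_, p = NA_real_))
      bc <- stats::coef(bf)
      c(K = exp(bc[["lK"]]), h = bc[["h"]],
        p = if (plateau) bc[["p"]] else NA_real_)
    }, numeric(3)))
  }
  ci <- if (!is.null(boot)) {
    apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  } else NULL
  structure(list(
    params = hill_params(exp(cf[["lK"]]), cf[["h"]], I_max = 1),
    plateau = if (plateau) cf[["p"]] else 0,
    ci = ci, residuals = stats::residuals(fit),
    n_boot = if (is.null(boot)) 0L else n_boot,
    column = column), class = "hc_hillfit")
}

#' @export
print.hc_hillfit <- function(x, ...) {
  cat(sprintf("<hc_hillfit> %s: IC50 = %.4g, h = %.3g",
              x$column, x$params$K, x$params$h))
  if (x$plateau > 0) cat(sprintf(", plateau = %.3g", x$plateau))
  if (!is.null(x$ci))
    cat(sprintf("  [K 95%% CI %.4g..%.4g, %d boot]",
                x$ci["2.5%", "K"], x$ci["97.5%", "K"], x$n_boot))
  cat("\n")
  invisible(x)
}

#' Fit Ca2+-substitution dose curves
#'
#' Same machinery as [fit_hill()] with the dose axis in mM external Ca2+.
#' The MET component is permitted a non-zero plateau (macroscopic MET
#' current saturates rather than vanishing at high Ca2+); the background /
#' leak component is fitted without one.
#'
#' @inheritParams fit_hill
#' @param column `"I_BG"` (no plateau) or `"I_MET"` (plateau term fitted).
#' @return An `hc_hillfit`.
#' @export
fit_ca_block <- function(tab, column = c("I_BG", "I_MET"), init = NULL,
                         n_boot = 500L, seed = 1L) {
  column <- match.arg(column)
  fit_hill(tab, column = column, init = init, n_boot = n_boot, seed = seed,
           plateau = (column == "I_MET"))
}
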