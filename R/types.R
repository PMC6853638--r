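#' Uniformly sampled patch-clamp trace
#'
#' The basic time-series container: a numeric vector of samples at a fixed
#' sampling rate, in either pA (membrane current, voltage clamp) or mV
#' (membrane potential, current clamp). Sign convention throughout the
#' package: inward current is negative.
#'
#' @param samples numeric vector, length >= 1. pA or mV according to `units`.
#' @param rate sampling rate in Hz (> 0). Typical rates are 1 kHz for slow
#'   baseline recordings, 50 kHz for I-V and current-clamp protocols and
#'   100 kHz for unitary-channel sweeps.
#' @param units `"pA"` or `"mV"`. Fixed for the lifetime of the trace.
#' @param t0 start time in seconds.
#' @return An object of class `hc_trace`.
#' @export
trace <- function(samples, rate, units = c("pA", "mV"), t0 = 0) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("a trace needs at least one sample")
  if (!is.finite(rate) || rate <= 0) stop("sampling rate must be > 0")
  structure(list(samples = samples, rate = as.numeric(rate), units = units,
                 t0 = as.numeric(t0)),
            class = "hc_trace")
}

#' Sample times of a trace
#' @param tr an `hc_trace`.
#' @return numeric vector of times in seconds (left edge of each sample).
#' @export
trace_times <- function(tr) {
  tr$t0 + (seq_along(tr$samples) - 1) / tr$rate
}

#' @export
length.hc_trace <- function(x) length(x$samples)

#' @export
print.hc_trace <- function(x, ...) {
  cat(sprintf("<hc_trace> %d samples @ %g Hz [%s], t0 = %g s, span %.4g s\n",
              length(x$samples), x$rate, x$units, x$t0,
              length(x$samples) / x$rate))
  invisible(x)
}

#' Perfusion or stimulus epoch
#'
#' Epochs annotate when a solution bathed the cell (track `"perfusion"`) or
#' when a stimulus was applied (track `"stimulus"`). Times are seconds from
#' recording start; intervals are half-open `[t_start, t_end)`. Epochs on
#' the same track must not overlap.
#'
#' @param label solution name, drug name or stimulus id.
#' @param t_start,t_end epoch bounds in seconds, `t_start < t_end`.
#' @param track `"perfusion"` or `"stimulus"`.
#' @return An object of class `hc_epoch`.
#' @export
epoch <- function(label, t_start, t_end, track = c("perfusion", "stimulus")) {
  track <- match.arg(track)
  if (!is.character(label) || length(label) != 1L)
    stop("epoch label must be a single string")
  if (!(t_start < t_end)) stop("epoch requires t_start < t_end")
  structure(list(label = label, t_start = as.numeric(t_start),
                 t_end = as.numeric(t_end), track = track),
            class = "hc_epoch")
}

#' External solution composition
#'
#' Ion concentrations in mM and blocker concentrations in uM. Only the
#' cations handled by the simulator are listed explicitly; Cl- is the
#' implied counter-ion.
#'
#' @param label unique solution name within a protocol.
#' @param Na,NMDG,K,Cs,Li,Ca,Mg,Ba,Zn,Co ion concentrations, mM.
#' @param DHS,dTC,amiloride,Gd,La blocker concentrations, uM
#'   (dihydrostreptomycin, d-tubocurarine, amiloride, Gd3+, La3+).
#' @return An object of class `hc_solution`.
#' @export
solution_spec <- function(label, Na = 0, NMDG = 0, K = 0, Cs = 0, Li = 0,
                          Ca = 0, Mg = 0, Ba = 0, Zn = 0, Co = 0,
                          DHS = 0, dTC = 0, amiloride = 0, Gd = 0, La = 0) {
  ions <- as.numeric(c(Na = Na, NMDG = NMDG, K = K, Cs = Cs, Li = Li,
                       Ca = Ca, Mg = Mg, Ba = Ba, Zn = Zn, Co = Co))
  names(ions) <- c("Na", "NMDG", "K", "Cs", "Li", "Ca", "Mg", "Ba", "Zn", "Co")
  blockers <- as.numeric(c(DHS = DHS, dTC = dTC, amiloride = amiloride,
                           Gd = Gd, La = La))
  names(blockers) <- c("DHS", "dTC", "amiloride", "Gd", "La")
  if (any(ions < 0) || any(blockers < 0))
    stop("all concentrations must be >= 0")
  if (!is.character(label) || length(label) != 1L)
    stop("solution label must be a single string")
  structure(list(label = label, ions = ions, blockers = blockers),
            class = "hc_solution")
}

#' Standard external solutions for the decomposition protocol
#'
#' Builds the three workhorse solutions: regular 144 mM Na+ recording
#' solution, the same solution plus dihydrostreptomycin (DHS), and the
#' impermeant-cation control in which NMDG+ replaces Na+. All three share
#' the same external Ca2+ so that perfusion switches do not change the
#' Ca2+-dependent terms of the model. Base composition (mM): 144 Na (or
#' NMDG), 5.8 K, 0.9 Mg, Ca as requested.
#'
#' @param ca_mM external Ca2+ in mM (default 1.3, the standard recording
#'   solution).
#' @param dhs_uM DHS concentration of the blocker solution, uM (default 100,
#'   the MET-working concentration).
#' @return named list of [solution_spec()] objects: `Na`, `NaDHS`, `NMDG`.
#' @export
standard_solutions <- function(ca_mM = 1.3, dhs_uM = 100) {
  list(
    Na = solution_spec("144Na", Na = 144, K = 5.8, Mg = 0.9, Ca = ca_mM),
    NaDHS = solution_spec("144Na+DHS", Na = 144, K = 5.8, Mg = 0.9,
                          Ca = ca_mM, DHS = dhs_uM),
    NMDG = solution_spec("144NMDG", NMDG = 144, K = 5.8, Mg = 0.9, Ca = ca_mM)
  )
}

#' Cell metadata
#'
#' @param genotype one of `"WT"`, `"Tmc1KO"`, `"Tmc2KO"`, `"Lhfpl5KO"`,
#'   `"Tmc1Tmc2DKO"`, or a `"transfected:<construct>"` string.
#' @param age postnatal day (integer).
#' @param cell_type `"OHC"` or `"IHC"`.
#' @param position fractional distance along the cochlear duct from the apex,
#'   in `[0, 1]` (apex = 0, base = 1). The canonical sampling positions are
#'   D05, D20, D40, D60 and D80 (0.05, 0.2, 0.4, 0.6, 0.8).
#' @param bundle_intact logical; `FALSE` marks cells whose hair bundle was
#'   removed before recording.
#' @return An object of class `hc_cellmeta`.
#' @export
cell_meta <- function(genotype = "WT", age = 6L, cell_type = c("OHC", "IHC"),
                      position = 0.155, bundle_intact = TRUE) {
  cell_type <- match.arg(cell_type)
  known <- c("WT", "Tmc1KO", "Tmc2KO", "Lhfpl5KO", "Tmc1Tmc2DKO")
  if (!(genotype %in% known || startsWith(genotype, "transfected:")))
    stop("unknown genotype: ", genotype)
  if (!is.finite(position) || position < 0 || position > 1)
    stop("position must lie in [0, 1]")
  position <- as.numeric(position)
  structure(list(genotype = genotype, age = as.integer(age),
                 cell_type = cell_type, position = position,
                 bundle_intact = isTRUE(bundle_intact)),
            class = "hc_cellmeta")
}

#' Default cell: wild-type P6 apical-middle outer hair cell
#'
#' The reference cell of the generative model. Its position (D = 0.155)
#' is where the tonotopic leak-current map equals the apical-middle cohort
#' mean of -51 pA, so tonotopic scaling is exactly 1 for this cell.
#'
#' @return An `hc_cellmeta`.
#' @export
default_meta <- function() cell_meta("WT", 6L, "OHC", 0.155, TRUE)

#' Whole-cell recording: traces + epochs + metadata
#'
#' The unit every analysis stage consumes. A voltage-clamp recording must
#' contain at least one current (pA) trace, a current-clamp recording at
#' least one voltage (mV) trace; the first trace with the mode's units is
#' the primary membrane trace. Auxiliary traces (command voltage, injected
#' current) may use other units.
#'
#' @param traces a single `hc_trace` or named list of them.
#' @param epochs list of [epoch()] objects. All epoch times must fall inside
#'   the union of trace time spans; same-track epochs must not overlap.
#' @param meta an [cell_meta()] object.
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param holding holding potential in mV (voltage clamp; default -70) or
#'   holding current in pA (current clamp; default 0).
#' @param solutions named list of [solution_spec()]s, keyed by the labels
#'   used in the perfusion epochs.
#' @return An object of class `hc_recording`.
#' @export
recording <- function(traces, epochs = list(), meta = default_meta(),
                      mode = c("voltage_clamp", "current_clamp"),
                      holding = if (mode[1] == "voltage_clamp") -70 else 0,
                      solutions = list()) {
  mode <- match.arg(mode)
  if (inherits(traces, "hc_trace")) traces <- list(Im = traces)
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "hc_trace")))
    stop("traces must be hc_trace objects")
  if (is.null(names(traces)) || any(names(traces) == ""))
    names(traces) <- paste0("trace", seq_along(traces))
  primary_units <- if (mode == "voltage_clamp") "pA" else "mV"
  if (!any(vapply(traces, function(tr) tr$units == primary_units, TRUE)))
    stop(sprintf("%s recording requires at least one %s trace",
                 mode, primary_units))
  if (!all(vapply(epochs, inherits, TRUE, "hc_epoch")))
    stop("epochs must be hc_epoch objects")
  check_epoch_overlap(epochs)
  spans <- vapply(traces, function(tr)
    c(tr$t0, tr$t0 + length(tr$samples) / tr$rate), numeric(2))
  tmin <- min(spans[1, ]); tmax <- max(spans[2, ])
  for (ep in epochs) {
    if (ep$t_start < tmin - 1e-9 || ep$t_end > tmax + 1e-9)
      stop(sprintf("epoch '%s' [%g, %g) lies outside the recorded span [%g, %g]",
                   ep$label, ep$t_start, ep$t_end, tmin, tmax))
  }
  if (length(solutions)) {
    if (!all(vapply(solutions, inherits, TRUE, "hc_solution")))
      stop("solutions must be hc_solution objects")
    names(solutions) <- vapply(solutions, `[[`, "", "label")
  }
  structure(list(traces = traces, epochs = epochs, meta = meta, mode = mode,
                 holding = as.numeric(holding), solutions = solutions),
            class = "hc_recording")
}

check_epoch_overlap <- function(epochs) {
  for (trk in c("perfusion", "stimulus")) {
    eps <- Filter(function(e) e$track == trk, epochs)
    if (length(eps) < 2L) next
    o <- order(vapply(eps, `[[`, 0, "t_start"))
    eps <- eps[o]
    for (i in seq_len(length(eps) - 1L)) {
      if (eps[[i]]$t_end > eps[[i + 1L]]$t_start + 1e-12)
        stop(sprintf("overlapping %s epochs: '%s' [%g, %g) and '%s' [%g, %g)",
                     trk, eps[[i]]$label, eps[[i]]$t_start, eps[[i]]$t_end,
                     eps[[i + 1L]]$label, eps[[i + 1L]]$t_start,
                     eps[[i + 1L]]$t_end))
    }
  }
  invisible(TRUE)
}

# primary membrane trace of a recording (first trace in the mode's units)
primary_trace <- function(rec) {
  u <- if (rec$mode == "voltage_clamp") "pA" else "mV"
  idx <- which(vapply(rec$traces, function(tr) tr$units == u, TRUE))[1]
  rec$traces[[idx]]
}

#' @export
print.hc_recording <- function(x, ...) {
  cat(sprintf("<hc_recording> %s, holding %g %s\n", x$mode, x$holding,
              if (x$mode == "voltage_clamp") "mV" else "pA"))
  cat(sprintf("  %d trace(s): %s\n", length(x$traces),
              paste(sprintf("%s (%d @ %g Hz, %s)", names(x$traces),
                            vapply(x$traces, length, 1L),
                            vapply(x$traces, `[[`, 0, "rate"),
                            vapply(x$traces, `[[`, "", "units")),
                    collapse = ", ")))
  cat(sprintf("  %d epoch(s); cell: %s %s P%d D=%.3g%s\n", length(x$epochs),
              x$meta$genotype, x$meta$cell_type, x$meta$age, x$meta$position,
              if (x$meta$bundle_intact) "" else " (bundle removed)"))
  invisible(x)
}

#' Binomial smoothing filter
#'
#' Repeated convolution with the (1/4, 1/2, 1/4) kernel; `passes = 20`
#' reproduces the "Binomial 20" display filter commonly applied to noisy
#' whole-cell current traces. Edge samples are replicated before each pass,
#' so the output has the same length and rate as the input and constants are
#' preserved exactly.
#'
#' @param tr an [trace()] with at least 3 samples.
#' @param passes number of kernel passes (>= 1).
#' @return the smoothed `hc_trace`.
#' @export
binomial_smooth <- function(tr, passes = 20L) {
  stopifnot(inherits(tr, "hc_trace"))
  passes <- as.integer(passes)
  if (passes < 1L) stop("passes must be >= 1")
  x <- tr$samples
  n <- length(x)
  if (n < 3L) stop("binomial smoothing needs a trace of at least 3 samples")
  for (p in seq_len(passes)) {
    xp <- c(x[1L], x, x[n])
    x <- 0.25 * xp[1:n] + 0.5 * xp[2:(n + 1L)] + 0.25 * xp[3:(n + 2L)]
  }
  trace(x, tr$rate, tr$units, tr$t0)
}

#' Steady-state baseline of a perfusion epoch
#'
#' Reads the "current baseline" of an epoch as the median of the samples in
#' the final `window_s` seconds of the epoch, i.e. after the perfusion
#' exchange has settled. The median is robust to residual transduction
#' events and brief artefacts. The default window is the final 20% of the
#' epoch, but no shorter than 0.5 s (clipped to the epoch duration).
#'
#' @param rec an [recording()].
#' @param epoch_label label of the perfusion epoch to read.
#' @param window_s averaging window in seconds; must be positive and no
#'   longer than the epoch.
#' @return baseline value in the primary trace's units (pA under voltage
#'   clamp), sign preserved.
#' @export
epoch_baseline <- function(rec, epoch_label, window_s = NULL) {
  stopifnot(inherits(rec, "hc_recording"))
  hit <- Filter(function(e) e$track == "perfusion" && e$label == epoch_label,
                rec$epochs)
  if (!length(hit))
    stop(sprintf("no perfusion epoch labelled '%s' in this recording",
                 epoch_label))
  ep <- hit[[1L]]
  dur <- ep$t_end - ep$t_start
  if (is.null(window_s)) window_s <- min(dur, max(0.2 * dur, 0.5))
  if (!is.finite(window_s) || window_s <= 0)
    stop("window_s must be > 0")
  if (window_s > dur + 1e-9)
    stop(sprintf("window_s (%g s) exceeds the duration of epoch '%s' (%g s)",
                 window_s, epoch_label, dur))
  tr <- primary_trace(rec)
  tt <- trace_times(tr)
  sel <- tt >= ep$t_end - window_s & tt < ep$t_end
  if (!any(sel))
    stop(sprintf("no samples fall inside the baseline window of epoch '%s'",
                 epoch_label))
  stats::median(tr$samples[sel])
}
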