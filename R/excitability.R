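## Current-clamp excitability analysis: spike detection, resting-state
## classification, ramp rheobase and F-I curves.

#' Detect action potentials in a membrane-potential trace
#'
#' A spike is an upward crossing of the dV/dt threshold followed within
#' 5 ms by a peak at least `min_height` mV above the pre-spike baseline
#' (median of the 20-5 ms window before onset). Onset voltage is the
#' membrane potential at the dV/dt crossing. A 3 ms refractory lockout
#' suppresses double counting on a single upstroke.
#'
#' @param vm a membrane-potential [trace()] (mV); current traces are
#'   rejected.
#' @param dvdt_thresh onset threshold, mV/ms (default 10).
#' @param min_height minimum peak height above baseline, mV (default 20).
#' @param lockout_s refractory lockout, s.
#' @return data.frame with columns `time` (s), `onset_v` (mV), `peak_v`
#'   (mV); zero rows when no spikes.
#' @export
detect_spikes <- function(vm, dvdt_thresh = 10, min_height = 20,
                          lockout_s = 0.003) {
  stopifnot(inherits(vm, "hc_trace"))
  if (vm$units != "mV")
    stop("spike detection needs a membrane-potential (mV) trace")
  v <- vm$samples
  rate <- vm$rate
  dvdt <- diff(v) * rate / 1000            # mV/ms
  up <- which(dvdt[-1] >= dvdt_thresh & dvdt[-length(dvdt)] < dvdt_thresh) + 1L
  peak_win <- max(1L, round(0.005 * rate))
  base_lo <- round(0.020 * rate); base_hi <- round(0.005 * rate)
  out <- list()
  last_t <- -Inf
  tt <- trace_times(vm)
  for (i in up) {
    if (tt[i] - last_t < lockout_s) next
    j2 <- min(length(v), i + peak_win)
    pk <- max(v[i:j2])
    b1 <- max(1L, i - base_lo); b2 <- max(1L, i - base_hi)
    base <- stats::median(v[b1:b2])
    if (pk - base < min_height) next
    out[[length(out) + 1L]] <- data.frame(time = tt[i], onset_v = v[i],
                                          peak_v = pk)
    last_t <- tt[i]
  }
  if (!length(out))
    return(data.frame(time = numeric(0), onset_v = numeric(0),
                      peak_v = numeric(0)))
  do.call(rbind, out)
}

#' Classify bursting and non-bursting resting states
#'
#' Tiles the trace into windows (default 1 s); windows holding at least
#' `min_spikes` spikes are bursting, the rest non-bursting; adjacent
#' same-state windows are merged. The per-state mean membrane potential is
#' computed on spike-blanked samples (+/- 10 ms around every spike
#' removed).
#'
#' @param vm a membrane-potential [trace()].
#' @param spikes spike table from [detect_spikes()].
#' @param window_s classification window (s).
#' @param min_spikes spikes per window that define bursting.
#' @param blank_s half-width of the spike blanking window (s).
#' @return data.frame of segments: `state`, `t_start`, `t_end`, `v_mean`.
#' @export
classify_states <- function(vm, spikes, window_s = 1, min_spikes = 2,
                            blank_s = 0.010) {
  stopifnot(inherits(vm, "hc_trace"))
  tt <- trace_times(vm)
  t_end <- vm$t0 + length(vm$samples) / vm$rate
  edges <- seq(vm$t0, t_end, by = window_s)
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
  n_win <- length(edges) - 1L
  counts <- if (nrow(spikes))
    tabulate(findInterval(spikes$time, edges, rightmost.closed = TRUE),
             nbins = n_win) else integer(n_win)
  state <- ifelse(counts >= min_spikes, "bursting", "non_bursting")
  blank <- rep(FALSE, length(vm$samples))
  for (ts in spikes$time)
    blank[tt >= ts - blank_s & tt <= ts + blank_s] <- TRUE
  segs <- list()
  k0 <- 1L
  for (k in seq_len(n_win)) {
    if (k < n_win && state[k + 1L] == state[k]) next
    sel <- tt >= edges[k0] & tt < edges[k + 1L] & !blank
    segs[[length(segs) + 1L]] <- data.frame(
      state = state[k], t_start = edges[k0], t_end = edges[k + 1L],
      v_mean = if (any(sel)) mean(vm$samples[sel]) else NA_real_)
    k0 <- k + 1L
  }
  do.call(rbind, segs)
}

#' Firing threshold and minimum injected current under a current ramp
#'
#' Detects the first spike during a ramp-current injection: the firing
#' threshold is the membrane potential at that spike's onset and the
#' minimum injected current (rheobase) is the injected-current value at the
#' onset time. With no spikes both are absent and the status flag says so.
#'
#' @param vm membrane-potential [trace()].
#' @param i_inj injected-current [trace()] aligned with `vm`.
#' @param ... passed to [detect_spikes()].
#' @return list: `v_threshold` (mV), `i_min` (pA), `status`
#'   (`"ok"` or `"no_spikes"`), `spikes` (the detection table).
#' @export
analyze_ramp_injection <- function(vm, i_inj, ...) {
  stopifnot(inherits(vm, "hc_trace"), inherits(i_inj, "hc_trace"))
  sp <- detect_spikes(vm, ...)
  if (!nrow(sp))
    return(list(v_threshold = NA_real_, i_min = NA_real_,
                status = "no_spikes", spikes = sp))
  t1 <- sp$time[1]
  idx <- pmin(length(i_inj$samples),
              pmax(1L, round((t1 - i_inj$t0) * i_inj$rate) + 1L))
  list(v_threshold = sp$onset_v[1], i_min = i_inj$samples[idx],
       status = "ok", spikes = sp)
}

#' F-I curve from a step-injection recording
#'
#' Counts spikes per second within every injected-current step epoch
#' (labels `i_step_<amp>`), returning the firing rate against injected
#' current ordered by amplitude.
#'
#' @param rec a current-clamp [recording()] with `i_step_*` stimulus
#'   epochs (e.g. from [simulate_current_clamp()] with
#'   [cc_step_protocol()]).
#' @param ... passed to [detect_spikes()].
#' @return data.frame `fi_points` with columns `i_inj` (pA) and
#'   `spikes_per_s`.
#' @export
fi_curve <- function(rec, ...) {
  stopifnot(inherits(rec, "hc_recording"))
  if (rec$mode != "current_clamp")
    stop("F-I analysis needs a current-clamp recording")
  steps <- Filter(function(e) e$track == "stimulus" &&
                    startsWith(e$label, "i_step_"), rec$epochs)
  if (!length(steps)) stop("no i_step_* stimulus epochs in this recording")
  sp <- detect_spikes(primary_trace(rec), ...)
  out <- do.call(rbind, lapply(steps, function(ep) {
    amp <- as.numeric(sub("^i_step_", "", ep$label))
    nsp <- if (nrow(sp)) sum(sp$time >= ep$t_start & sp$time < ep$t_end)
      else 0L
    data.frame(i_inj = amp, spikes_per_s = nsp / (ep$t_end - ep$t_start))
  }))
  out[order(out$i_inj), , drop = FALSE]
}
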