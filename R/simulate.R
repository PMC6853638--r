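## Stimulus and protocol builders -------------------------------------------

#' Stimulus descriptors for protocol segments
#'
#' `stim_none()` no stimulus; `stim_fj_sine()` sinusoidal fluid-jet bundle
#' deflection; `stim_probe_step()` a train of glass-probe step deflections;
#' `stim_v_ramp()` a voltage ramp (voltage clamp); `stim_i_ramp()` /
#' `stim_i_step()` injected-current ramp / step (current clamp).
#'
#' @param freq_hz sine frequency (Hz); the fluid-jet standard is 40 Hz.
#' @param amp_nm deflection amplitude (nm); 800 nm saturates the
#'   transducer, 100 nm is the unitary-recording step.
#' @param dur_s step duration within each period (s).
#' @param period_s step repetition period (s); 0.1 s gives the 10 Hz train.
#' @param from,to ramp endpoints (mV for voltage, pA for current). The ramp
#'   spans its whole segment.
#' @param amp_pA injected step amplitude (pA).
#' @name stimuli
NULL

#' @rdname stimuli
#' @export
stim_none <- function() list(type = "none")

#' @rdname stimuli
#' @export
stim_fj_sine <- function(freq_hz = 40, amp_nm = 400)
  list(type = "fj_sine", freq_hz = freq_hz, amp_nm = amp_nm)

#' @rdname stimuli
#' @export
stim_probe_step <- function(amp_nm = 800, dur_s = 0.05, period_s = 0.1)
  list(type = "probe_step", amp_nm = amp_nm, dur_s = dur_s,
       period_s = period_s)

#' @rdname stimuli
#' @export
stim_v_ramp <- function(from = -120, to = 80)
  list(type = "v_ramp", from = from, to = to)

#' @rdname stimuli
#' @export
stim_i_ramp <- function(from = -100, to = 100)
  list(type = "i_ramp", from = from, to = to)

#' @rdname stimuli
#' @export
stim_i_step <- function(amp_pA)
  list(type = "i_step", amp_pA = amp_pA)

#' Assemble a recording protocol
#'
#' A protocol is an ordered list of segments, each pairing a solution label
#' with a duration and an optional stimulus, plus the sampling rate and
#' clamp mode. Stimulus types must be legal for the mode (bundle deflection
#' and voltage ramps under voltage clamp; current injection under current
#' clamp).
#'
#' @param segments list of segments from [proto_seg()].
#' @param solutions named list of [solution_spec()]s covering every label
#'   used by the segments.
#' @param mode clamp mode.
#' @param rate_hz sampling rate.
#' @return An object of class `hc_protocol`.
#' @export
protocol <- function(segments, solutions,
                     mode = c("voltage_clamp", "current_clamp"),
                     rate_hz = 1000) {
  mode <- match.arg(mode)
  vc_ok <- c("none", "fj_sine", "probe_step", "v_ramp")
  cc_ok <- c("none", "i_ramp", "i_step")
  names(solutions) <- vapply(solutions, `[[`, "", "label")
  for (sg in segments) {
    if (!sg$duration > 0) stop("segment durations must be > 0")
    if (is.null(solutions[[sg$solution]]))
      stop("unknown solution label: ", sg$solution)
    legal <- if (mode == "voltage_clamp") vc_ok else cc_ok
    if (!(sg$stimulus$type %in% legal))
      stop(sprintf("stimulus '%s' is not legal under %s",
                   sg$stimulus$type, mode))
  }
  structure(list(segments = segments, solutions = solutions, mode = mode,
                 rate_hz = rate_hz),
            class = "hc_protocol")
}

#' @rdname protocol
#' @param solution solution label for a segment.
#' @param duration segment duration, s.
#' @param stimulus a stimulus descriptor (see [stimuli]).
#' @export
proto_seg <- function(solution, duration, stimulus = stim_none())
  list(solution = solution, duration = duration, stimulus = stimulus)

#' Canned protocols
#'
#' * `decomposition_protocol()`: the Na -> Na+DHS -> NMDG -> Na perfusion
#'   sequence used to split the background current into leak and resting-MET
#'   components (1 kHz).
#' * `fj_decomposition_protocol()`: the same with a fluid-jet sine segment
#'   before the DHS step, for the mechanically-closed baseline readout.
#' * `ramp_iv_protocol()`: settling segment then a -120 to +80 mV ramp
#'   (2 s, 50 kHz) in a chosen test solution, for reversal-potential work.
#' * `cc_rest_protocol()`, `cc_ramp_protocol()`, `cc_step_protocol()`:
#'   current-clamp resting recording, -100 to +100 pA ramp injection, and
#'   the -50 to +125 pA (25 pA increment) step family.
#'
#' @param ca_mM external Ca2+ (mM) shared by the solutions.
#' @param dhs_uM DHS concentration of the blocker segment (uM).
#' @param seg_s duration of each main perfusion segment (s).
#' @param wash_s duration of the final Na wash segment (0 to omit).
#' @param rate_hz sampling rate.
#' @name canned_protocols
#' @export
decomposition_protocol <- function(ca_mM = 1.3, dhs_uM = 100, seg_s = 8,
                                   wash_s = 4, rate_hz = 1000) {
  sols <- standard_solutions(ca_mM, dhs_uM)
  segs <- list(proto_seg("144Na", seg_s),
               proto_seg("144Na+DHS", seg_s),
               proto_seg("144NMDG", seg_s))
  if (wash_s > 0) segs <- c(segs, list(proto_seg("144Na", wash_s)))
  protocol(segs, sols, "voltage_clamp", rate_hz)
}

#' @rdname canned_protocols
#' @param fj_amp_nm fluid-jet sine amplitude (nm).
#' @param fj_s duration of the sine segment (s).
#' @export
fj_decomposition_protocol <- function(ca_mM = 0.3, dhs_uM = 100, seg_s = 8,
                                      fj_s = 4, fj_amp_nm = 400,
                                      rate_hz = 1000) {
  sols <- standard_solutions(ca_mM, dhs_uM)
  protocol(list(
    proto_seg("144Na", seg_s),
    proto_seg("144Na", fj_s, stim_fj_sine(40, fj_amp_nm)),
    proto_seg("144Na+DHS", seg_s),
    proto_seg("144NMDG", seg_s)
  ), sols, "voltage_clamp", rate_hz)
}

#' @rdname canned_protocols
#' @param solution an [solution_spec()] for the ramp segment.
#' @param pre_s settling time before the ramp (s).
#' @param ramp_s ramp duration (s).
#' @export
ramp_iv_protocol <- function(solution, pre_s = 1, ramp_s = 2,
                             rate_hz = 50000) {
  protocol(list(proto_seg(solution$label, pre_s),
                proto_seg(solution$label, ramp_s, stim_v_ramp(-120, 80))),
           list(solution), "voltage_clamp", rate_hz)
}

#' @rdname canned_protocols
#' @param duration resting-recording duration (s).
#' @export
cc_rest_protocol <- function(duration = 10, ca_mM = 1.3, dhs_uM = 100,
                             rate_hz = 10000) {
  sols <- standard_solutions(ca_mM, dhs_uM)
  protocol(list(proto_seg("144Na+DHS", duration)), sols,
           "current_clamp", rate_hz)
}

#' @rdname canned_protocols
#' @param from,to injected-current ramp endpoints (pA).
#' @param ramp_s current-ramp duration (s).
#' @export
cc_ramp_protocol <- function(from = -100, to = 100, ramp_s = 3, pre_s = 0.5,
                             ca_mM = 1.3, dhs_uM = 100, rate_hz = 50000) {
  sols <- standard_solutions(ca_mM, dhs_uM)
  protocol(list(proto_seg("144Na+DHS", pre_s),
                proto_seg("144Na+DHS", ramp_s, stim_i_ramp(from, to))),
           sols, "current_clamp", rate_hz)
}

#' @rdname canned_protocols
#' @param amps injected step amplitudes (pA).
#' @param step_s step duration (s).
#' @param gap_s rest between steps (s).
#' @export
cc_step_protocol <- function(amps = seq(-50, 125, by = 25), step_s = 1,
                             gap_s = 0.5, ca_mM = 1.3, dhs_uM = 100,
                             rate_hz = 10000) {
  sols <- standard_solutions(ca_mM, dhs_uM)
  segs <- list(proto_seg("144Na+DHS", gap_s))
  for (a in amps) {
    segs <- c(segs, list(proto_seg("144Na+DHS", step_s, stim_i_step(a)),
                         proto_seg("144Na+DHS", gap_s)))
  }
  protocol(segs, sols, "current_clamp", rate_hz)
}

## Voltage-clamp simulation --------------------------------------------------

# per-sample solution composition with exponential perfusion mixing
mix_solutions <- function(protocol, t, seg_idx, tau) {
  fields <- c(names(protocol$solutions[[1]]$ions),
              names(protocol$solutions[[1]]$blockers))
  targets <- vapply(protocol$segments, function(sg) {
    s <- protocol$solutions[[sg$solution]]
    c(s$ions, s$blockers)
  }, numeric(length(fields)))
  rownames(targets) <- fields
  starts <- cumsum(c(0, vapply(protocol$segments, `[[`, 0, "duration")))
  conc <- matrix(0, nrow = length(t), ncol = length(fields),
                 dimnames = list(NULL, fields))
  state <- targets[, 1]  # pre-equilibrated in the first solution
  for (k in seq_along(protocol$segments)) {
    sel <- seg_idx == k
    if (!any(sel)) next
    dt <- t[sel] - starts[k]
    decay <- if (tau > 0) exp(-dt / tau) else rep(0, length(dt))
    for (f in fields)
      conc[sel, f] <- targets[f, k] + (state[f] - targets[f, k]) * decay
    end_decay <- if (tau > 0) exp(-(starts[k + 1] - starts[k]) / tau) else 0
    state <- targets[, k] + (state - targets[, k]) * end_decay
  }
  conc
}

# sample index -> segment index given segment durations
segment_index <- function(t, durations) {
  starts <- cumsum(c(0, durations))
  findInterval(t, starts, rightmost.closed = FALSE,
               left.open = FALSE)
}

#' Simulate a whole-cell voltage-clamp recording
#'
#' Generates a membrane-current trace under a perfusion/stimulus protocol
#' from the model described in [default_config()]: an ohmic,
#' cation-dependent, Ca2+-blockable leak; a mechanotransducer population
#' with Boltzmann activation and Ca2+-dependent resting open probability;
#' a technical seal leak; and white Gaussian noise. Perfusion switches mix
#' exponentially (`config$perfusion_tau`), producing realistic transients.
#' Deterministic given `(config, protocol, meta, seed)`.
#'
#' The returned recording carries a `truth` attribute with the steady-state
#' components of every segment (from [steady_components()]).
#'
#' @param config an [default_config()]-style configuration.
#' @param protocol an [protocol()] with `mode = "voltage_clamp"`.
#' @param meta an [cell_meta()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param noise logical; `FALSE` for noiseless traces.
#' @return an [recording()] with trace `Im` (and `Vcmd` when the protocol
#'   drives voltage).
#' @export
simulate_voltage_clamp <- function(config, protocol, meta = default_meta(),
                                   seed = config$seed, noise = TRUE) {
  stopifnot(inherits(config, "hc_simconfig"), inherits(protocol, "hc_protocol"))
  if (protocol$mode != "voltage_clamp")
    stop("protocol mode must be voltage_clamp")
  set.seed(seed)
  rate <- protocol$rate_hz
  durations <- vapply(protocol$segments, `[[`, 0, "duration")
  total <- sum(durations)
  n <- round(total * rate)
  t <- (seq_len(n) - 1) / rate
  seg_idx <- pmin(segment_index(t, durations), length(durations))
  conc <- mix_solutions(protocol, t, seg_idx, config$perfusion_tau)

  holding <- -70
  V <- rep(holding, n)
  x <- numeric(n)
  starts <- cumsum(c(0, durations))
  epochs <- list()
  for (k in seq_along(protocol$segments)) {
    sg <- protocol$segments[[k]]
    epochs <- c(epochs, list(epoch(sg$solution, starts[k], starts[k + 1],
                                   "perfusion")))
    st <- sg$stimulus
    sel <- seg_idx == k
    dt <- t[sel] - starts[k]
    if (st$type == "fj_sine") {
      x[sel] <- st$amp_nm * sin(2 * pi * st$freq_hz * dt)
      epochs <- c(epochs, list(epoch(sprintf("fj_sine_%gHz", st$freq_hz),
                                     starts[k], starts[k + 1], "stimulus")))
    } else if (st$type == "probe_step") {
      x[sel] <- ifelse(dt %% st$period_s < st$dur_s, st$amp_nm, 0)
      epochs <- c(epochs, list(epoch("probe_step", starts[k], starts[k + 1],
                                     "stimulus")))
    } else if (st$type == "v_ramp") {
      V[sel] <- st$from + (st$to - st$from) * dt / sg$duration
      epochs <- c(epochs, list(epoch("v_ramp", starts[k], starts[k + 1],
                                     "stimulus")))
    }
  }

  s <- genotype_position_scales(config, meta)
  fcat <- leak_cation_fraction(as.data.frame(conc))
  b_ca <- leak_ca_factor(config, conc[, "Ca"])
  blockers <- lapply(colnames(conc)[colnames(conc) %in%
                                      names(config$leak$drug_block)],
                     function(f) conc[, f])
  names(blockers) <- colnames(conc)[colnames(conc) %in%
                                      names(config$leak$drug_block)]
  b_leak <- if (config$leak$apply_drug_block)
    drug_block_factor(config$leak$drug_block, blockers) else 1
  g_leak <- config$leak$g_max * s$leak * fcat * b_ca * b_leak
  i_leak <- g_leak * (V - config$leak$E_rev)

  p_rest <- p_open_rest_at(config, conc[, "Ca"])
  p_open <- boltzmann_p_open(config, x, p_rest)
  p_open[x == 0] <- p_rest[x == 0]   # exact resting value when unstimulated
  b_met <- drug_block_factor(config$met$drug_block, blockers)
  # MET amplitude per Ca2+ regime at this cell's position
  a_low <- met_amplitude_at(config, meta, 1)
  a_high <- met_amplitude_at(config, meta, config$met$high_ca_mM)
  a_met <- ifelse(conc[, "Ca"] >= config$met$high_ca_mM, a_high, a_low)
  i_met <- a_met * p_open * b_met * fcat * V / 70
  i_seal <- config$seal$g_seal * V

  im <- i_leak + i_met + i_seal
  if (noise)
    im <- im + stats::rnorm(n, 0, config$noise$sigma_pA * sqrt(rate / 1000))

  traces <- list(Im = trace(im, rate, "pA"))
  if (any(V != holding)) traces$Vcmd <- trace(V, rate, "mV")
  rec <- recording(traces, epochs, meta, "voltage_clamp", holding,
                   protocol$solutions)
  truth <- lapply(protocol$segments, function(sg)
    steady_components(config, protocol$solutions[[sg$solution]], meta,
                      holding))
  names(truth) <- vapply(protocol$segments, `[[`, "", "solution")
  attr(rec, "truth") <- list(segments = truth, seed = seed)
  rec
}

## Unitary-channel simulation ------------------------------------------------

# two-state Markov open mask over n samples at dt, starting closed
gate_two_state <- function(n, dt, k_open, k_close) {
  open <- logical(n)
  i <- 1L
  state <- FALSE
  while (i <= n) {
    k <- if (state) k_close else k_open
    dwell_n <- if (k <= 0) n else max(1L, ceiling(stats::rexp(1, k) / dt))
    j <- min(n, i + dwell_n - 1L)
    if (state) open[i:j] <- TRUE
    i <- j + 1L
    state <- !state
  }
  open
}

#' Simulate unitary MET channel sweeps
#'
#' Two-state (closed/open) Markov gating of a single MET channel sampled at
#' 100 kHz, aligned to a 100 nm probe-step epoch; the open-state current is
#' the tonotopic unitary amplitude for the cell's position and Ca2+ regime,
#' with Gaussian noise at the post-filter rms. Sweeps are baseline-
#' subtracted (closed level 0). Outside the step the channel stays shut.
#'
#' @param config an [default_config()]-style configuration (gating rates in
#'   `config$met$gating_rates`; `k_open = 0` gives an absorbing closed
#'   state, negative rates or non-positive `k_close` are rejected).
#' @param meta an [cell_meta()]; `meta$position` selects the unitary map
#'   entry.
#' @param n_sweeps number of sweeps.
#' @param ca_mM external Ca2+ (3 and 35 are the standard regimes).
#' @param seed RNG seed.
#' @param noise logical.
#' @param pre_s,step_s,post_s sweep timing (s).
#' @param rate_hz sampling rate (100 kHz standard).
#' @return an [recording()] whose traces `sweep_001`, ... are the aligned
#'   sweeps, with a shared `probe_step` stimulus epoch and a `truth`
#'   attribute (`i_unit`, stationary open probability).
#' @export
simulate_single_channel <- function(config, meta = default_meta(),
                                    n_sweeps = 30, ca_mM = 3,
                                    seed = config$seed, noise = TRUE,
                                    pre_s = 0.02, step_s = 0.06,
                                    post_s = 0.02, rate_hz = 1e5) {
  stopifnot(inherits(config, "hc_simconfig"))
  gr <- config$met$gating_rates
  if (gr$k_open < 0 || gr$k_close <= 0)
    stop("gating rates must satisfy k_open >= 0, k_close > 0")
  set.seed(seed)
  i_u <- unitary_current_at(config, meta$position, ca_mM)
  # cell-to-cell scatter of the unitary amplitude (biological variability)
  cv <- config$met$i_unit_cv
  if (!is.null(cv) && cv > 0 && noise)
    i_u <- i_u * (1 + cv * stats::rnorm(1))
  rate <- rate_hz
  n_pre <- round(pre_s * rate); n_step <- round(step_s * rate)
  n_post <- round(post_s * rate)
  n <- n_pre + n_step + n_post
  sigma <- if (noise) config$noise$sc_sigma_pA else 0
  traces <- list()
  for (sw in seq_len(n_sweeps)) {
    open <- gate_two_state(n_step, 1 / rate, gr$k_open, gr$k_close)
    y <- c(numeric(n_pre), i_u * open, numeric(n_post))
    if (sigma > 0) y <- y + stats::rnorm(n, 0, sigma)
    traces[[sprintf("sweep_%03d", sw)]] <- trace(y, rate, "pA")
  }
  ep <- list(epoch("probe_step", pre_s, pre_s + step_s, "stimulus"))
  rec <- recording(traces, ep, meta, "voltage_clamp", -70,
                   list(solution_spec(sprintf("%gCa", ca_mM), Na = 144,
                                      K = 5.8, Ca = ca_mM)))
  attr(rec, "truth") <- list(
    i_unit = i_u,
    p_open = gr$k_open / (gr$k_open + gr$k_close),
    step_window = c(pre_s, pre_s + step_s), seed = seed)
  rec
}

## Current-clamp simulation --------------------------------------------------

#' Simulate an inner-hair-cell current-clamp recording
#'
#' Leaky integrate-and-fire membrane: `dV/dt = (-g_tot (V - V_rest) +
#' I_inj) / C`, with a stereotyped spike waveform inserted whenever V
#' crosses threshold, followed by reset and an absolute refractory period.
#' Genotype shifts the resting potential (`config$ihc$V_rest`); a slow
#' sinusoidal drive (`config$ihc$burst`) emulates spontaneous bursting when
#' enabled. This generator is phenomenological -- it exists to exercise
#' spike detection, threshold and F-I analysis, not to model IHC
#' conductances.
#'
#' Analytic contract used by tests: under a slow current ramp the first
#' spike occurs where the quasi-steady potential reaches threshold, i.e. at
#' `I_min = g_tot (V_th - V_rest)` up to the integrator lag
#' `tau * dI/dt`.
#'
#' @inheritParams simulate_voltage_clamp
#' @param protocol a current-clamp [protocol()].
#' @return an [recording()] with traces `Vm` (mV) and `Iinj` (pA) and a
#'   `truth` attribute (inserted spike times, parameters, analytic
#'   rheobase).
#' @export
simulate_current_clamp <- function(config, protocol, meta = default_meta(),
                                   seed = config$seed, noise = TRUE) {
  stopifnot(inherits(config, "hc_simconfig"), inherits(protocol, "hc_protocol"))
  if (protocol$mode != "current_clamp")
    stop("protocol mode must be current_clamp")
  set.seed(seed)
  p <- config$ihc
  rate <- protocol$rate_hz
  dt_ms <- 1000 / rate
  durations <- vapply(protocol$segments, `[[`, 0, "duration")
  starts <- cumsum(c(0, durations))
  n <- round(sum(durations) * rate)
  t <- (seq_len(n) - 1) / rate

  i_inj <- numeric(n)
  epochs <- list()
  seg_idx <- pmin(segment_index(t, durations), length(durations))
  for (k in seq_along(protocol$segments)) {
    sg <- protocol$segments[[k]]
    epochs <- c(epochs, list(epoch(sg$solution, starts[k], starts[k + 1],
                                   "perfusion")))
    sel <- seg_idx == k
    dts <- t[sel] - starts[k]
    st <- sg$stimulus
    if (st$type == "i_ramp") {
      i_inj[sel] <- st$from + (st$to - st$from) * dts / sg$duration
      epochs <- c(epochs, list(epoch("i_ramp", starts[k], starts[k + 1],
                                     "stimulus")))
    } else if (st$type == "i_step") {
      i_inj[sel] <- st$amp_pA
      epochs <- c(epochs, list(epoch(sprintf("i_step_%+g", st$amp_pA),
                                     starts[k], starts[k + 1], "stimulus")))
    }
  }

  v_rest <- p$V_rest[[meta$genotype]]
  if (is.null(v_rest) || is.na(v_rest)) v_rest <- p$V_rest[["WT"]]
  drive <- if (isTRUE(p$burst$on))
    p$burst$amp_mV * sin(2 * pi * p$burst$freq_hz * t) else numeric(n)
  i_noise <- if (noise)
    stats::rnorm(n, 0, config$noise$sigma_pA * sqrt(rate / 1000)) else
      numeric(n)

  n_rise <- max(2L, round(p$spike_rise_ms / dt_ms))
  n_fall <- max(2L, round(p$spike_fall_ms / dt_ms))
  peak <- p$V_th + p$spike_peak_rise

  V <- numeric(n)
  v <- v_rest
  refrac_until <- -Inf
  spike_times <- numeric(0)
  i <- 1L
  g <- p$g_tot_nS
  C <- p$C_pF
  while (i <= n) {
    if (v >= p$V_th && t[i] >= refrac_until) {
      wave <- c(seq(v, peak, length.out = n_rise + 1L)[-1L],
                seq(peak, p$V_reset, length.out = n_fall + 1L)[-1L])
      j <- min(n, i + length(wave) - 1L)
      V[i:j] <- wave[seq_len(j - i + 1L)]
      spike_times <- c(spike_times, t[i])
      refrac_until <- t[i] + p$t_refrac
      v <- p$V_reset
      i <- j + 1L
    } else {
      V[i] <- v
      dv <- dt_ms * (-g * (v - (v_rest + (if (length(drive)) drive[i] else 0))) +
                       i_inj[i] + i_noise[i]) / C
      v <- v + dv
      # refractory shunt: the membrane cannot re-depolarize past threshold
      if (t[i] < refrac_until && v > p$V_th) v <- p$V_th
      i <- i + 1L
    }
  }

  rec <- recording(list(Vm = trace(V, rate, "mV"),
                        Iinj = trace(i_inj, rate, "pA")),
                   epochs, meta, "current_clamp", 0, protocol$solutions)
  attr(rec, "truth") <- list(
    spike_times = spike_times, n_spikes = length(spike_times),
    v_rest = v_rest, g_tot = g, V_th = p$V_th,
    i_min_analytic = g * (p$V_th - v_rest),
    tau_ms = C / g, seed = seed)
  rec
}
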