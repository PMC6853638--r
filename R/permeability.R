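## Reversal potentials and Goldman-Hodgkin-Katz permeability ratios.
##
## Physical constants (SI): Faraday and gas constants; potentials are mV,
## so E*F/(R*T) uses E/1000.
.F_CONST <- 96485.33212
.R_CONST <- 8.31446261815324

#' Ramp I-V container
#'
#' Paired voltage/current arrays from a voltage-ramp protocol (standard:
#' -120 to +80 mV over 2 s). Voltage must be strictly increasing.
#'
#' @param voltage mV, strictly monotone increasing.
#' @param current pA, same length.
#' @return An object of class `hc_rampiv`.
#' @export
ramp_iv <- function(voltage, current) {
  if (length(voltage) != length(current))
    stop("voltage and current must have equal length")
  if (any(diff(voltage) <= 0))
    stop("ramp voltage must be strictly monotone increasing")
  structure(list(voltage = as.numeric(voltage),
                 current = as.numeric(current)), class = "hc_rampiv")
}

#' Extract a ramp I-V from a simulated recording
#'
#' Pulls the samples inside a `v_ramp` stimulus epoch, pairing the command
#' voltage trace with the current trace.
#'
#' @param rec a voltage-clamp [recording()] containing traces `Im` and
#'   `Vcmd` and a `v_ramp` stimulus epoch.
#' @param epoch_label stimulus epoch label (default `"v_ramp"`).
#' @return An [ramp_iv()].
#' @export
extract_ramp <- function(rec, epoch_label = "v_ramp") {
  stopifnot(inherits(rec, "hc_recording"))
  hit <- Filter(function(e) e$track == "stimulus" && e$label == epoch_label,
                rec$epochs)
  if (!length(hit)) stop("no stimulus epoch labelled '", epoch_label, "'")
  ep <- hit[[1]]
  if (is.null(rec$traces$Vcmd) || is.null(rec$traces$Im))
    stop("recording must carry Im and Vcmd traces")
  tt <- trace_times(rec$traces$Im)
  sel <- tt >= ep$t_start & tt < ep$t_end
  v <- rec$traces$Vcmd$samples[sel]
  i <- rec$traces$Im$samples[sel]
  keep <- c(TRUE, diff(v) > 0)
  ramp_iv(v[keep], i[keep])
}

#' Subtract the technical-leak ramp recorded in NMDG
#'
#' Pointwise current difference of two ramps on a shared voltage grid; a
#' mismatched grid is first resampled onto the test ramp's grid by linear
#' interpolation (the interpolation error is bounded by grid spacing times
#' the local I-V slope).
#'
#' @param ramp test-solution [ramp_iv()].
#' @param nmdg_ramp NMDG-solution [ramp_iv()] from the same cell.
#' @return An [ramp_iv()] on `ramp`'s voltage grid.
#' @export
subtract_technical_leak <- function(ramp, nmdg_ramp) {
  stopifnot(inherits(ramp, "hc_rampiv"), inherits(nmdg_ramp, "hc_rampiv"))
  lo <- max(min(ramp$voltage), min(nmdg_ramp$voltage))
  hi <- min(max(ramp$voltage), max(nmdg_ramp$voltage))
  if (lo >= hi) stop("ramps cover disjoint voltage ranges")
  keep <- ramp$voltage >= lo & ramp$voltage <= hi
  v <- ramp$voltage[keep]
  i_nmdg <- stats::approx(nmdg_ramp$voltage, nmdg_ramp$current, xout = v)$y
  ramp_iv(v, ramp$current[keep] - i_nmdg)
}

#' Estimate the reversal potential from a ramp I-V
#'
#' Fits a straight line to the inward (negative-current) portion of the
#' ramp and returns its zero-crossing voltage. The inward portion is
#' delimited by a voltage cutoff: the first voltage at which the smoothed
#' trace comes within `2 * noise_rms` of zero. Selecting by voltage rather
#' than by each sample's own (noisy) current avoids truncating the noise
#' distribution, which would bias the fitted line. When the current never
#' approaches zero the whole inward limb is used and the crossing is
#' extrapolated.
#'
#' @param ramp an [ramp_iv()].
#' @param noise_rms current noise rms (pA); estimated from first differences
#'   (`sd(diff(I)) / sqrt(2)`) when `NULL`.
#' @param smooth_n running-mean width (samples) used to locate the cutoff.
#' @return reversal potential, mV.
#' @export
estimate_reversal <- function(ramp, noise_rms = NULL, smooth_n = 25) {
  stopifnot(inherits(ramp, "hc_rampiv"))
  v <- ramp$voltage; i <- ramp$current
  if (all(i >= 0))
    stop("ramp current is nowhere inward; no reversal to estimate")
  if (is.null(noise_rms)) noise_rms <- stats::sd(diff(i)) / sqrt(2)
  ism <- if (noise_rms > 0 && length(i) >= 3 * smooth_n)
    as.numeric(stats::filter(i, rep(1 / smooth_n, smooth_n), sides = 2))
  else i
  near_zero <- which(!is.na(ism) & ism >= -2 * noise_rms)
  v_cut <- if (length(near_zero)) v[near_zero[1]] else max(v) + 1
  sel <- v < v_cut
  if (sum(sel) < 10)
    stop("fewer than 10 inward samples below the crossing; cannot fit")
  fit <- stats::lm(i[sel] ~ v[sel])
  slope <- stats::coef(fit)[[2]]
  if (!is.finite(slope) || slope <= 0)
    stop("inward limb has non-positive slope; crossing is not monotone")
  -stats::coef(fit)[[1]] / slope
}

#' Monovalent permeability ratio from a reversal potential
#'
#' `P_X / P_Cs = [Cs]_i * exp(E_rev F / R T) / [X]_o` for a bi-ionic
#' condition with internal Cs+ and a monovalent external test cation.
#'
#' @param E_rev reversal potential, mV.
#' @param Cs_i internal Cs+ concentration, mM (150 is the standard
#'   permeability-protocol pipette value; 140 the general-recording one).
#' @param X_o external test-ion concentration, mM.
#' @param T_K absolute temperature (default 298.15 K, i.e. 25 C).
#' @return list with `P_ratio` (P_X/P_Cs) and `E_rev_used` (mV).
#' @export
perm_ratio_monovalent <- function(E_rev, Cs_i = 150, X_o, T_K = 298.15) {
  stopifnot(Cs_i > 0, X_o > 0, T_K > 0)
  u <- exp(E_rev / 1000 * .F_CONST / (.R_CONST * T_K))
  list(P_ratio = Cs_i * u / X_o, E_rev_used = E_rev)
}

#' Divalent permeability ratio with activity coefficients
#'
#' Fatt-Ginsborg bi-ionic form for a divalent external test cation against
#' internal Cs+:
#' `P_X / P_Cs = gamma_Cs [Cs]_i e^u (e^u + 1) / (4 gamma_X [X]_o)` with
#' `u = E_rev F / (R T)`. Standard activity coefficients: gamma_Cs = 0.70,
#' gamma_Ca = 0.4657, gamma_Mg = 0.5271. (Some printed versions of this
#' equation omit F inside the bracket's exponent; dimensional analysis
#' requires `exp(E_rev F / R T)` in both factors, as implemented here.)
#'
#' @inheritParams perm_ratio_monovalent
#' @param gamma_X activity coefficient of the test ion, in (0, 1].
#' @param gamma_Cs activity coefficient of internal Cs+.
#' @return list with `P_ratio` and `E_rev_used`.
#' @export
perm_ratio_divalent <- function(E_rev, Cs_i = 150, X_o, gamma_X,
                                gamma_Cs = 0.70, T_K = 298.15) {
  stopifnot(Cs_i > 0, X_o > 0, T_K > 0,
            gamma_X > 0, gamma_X <= 1, gamma_Cs > 0, gamma_Cs <= 1)
  u <- exp(E_rev / 1000 * .F_CONST / (.R_CONST * T_K))
  list(P_ratio = gamma_Cs * Cs_i * u * (u + 1) / (4 * gamma_X * X_o),
       E_rev_used = E_rev)
}
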