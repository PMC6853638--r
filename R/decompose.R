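## Background-current decomposition by ionic substitution.
##
## The background current is defined by subtraction of steady baselines:
##   I_BG   = I_Na - I_NMDG         (excludes the technical seal leak)
##   I_Leak = I_DHS - I_NMDG        (MET-independent leak)
##   I_RestingMET = I_Na - I_DHS    (DHS-sensitive resting MET current)
## so that I_BG = I_Leak + I_RestingMET is an arithmetic identity whenever
## a DHS epoch is present.

# classify a perfusion epoch's solution: "Na", "DHS" (Na + DHS) or "NMDG"
classify_solution <- function(sol) {
  if (sol$ions[["NMDG"]] >= 100) return("NMDG")
  if (sol$ions[["Na"]] >= 100 && sol$blockers[["DHS"]] > 0) return("DHS")
  if (sol$ions[["Na"]] >= 100) return("Na")
  NA_character_
}

#' Decompose a perfusion recording into background, leak and resting-MET
#' currents
#'
#' Reads steady-state baselines (via [epoch_baseline()]) from the first
#' Na-containing, first DHS-containing and first NMDG perfusion epochs and
#' forms the subtraction-defined components. When several Na epochs exist
#' (wash-in / wash-out), the first defines `I_Na`; later ones are reported
#' as recovery baselines. Without a DHS epoch only `I_BG` is computed.
#' Quality control follows the standard rule: a cell passes when its
#' baseline magnitude in NMDG is below 20 pA (strict).
#'
#' @param rec a voltage-clamp [recording()] whose `solutions` table allows
#'   the perfusion epochs to be classified.
#' @param window_s baseline window passed to [epoch_baseline()] (default:
#'   final 20% of each epoch, minimum 0.5 s).
#' @return An object of class `hc_decomp` (also a one-row data.frame) with
#'   columns `I_Na`, `I_NMDG`, `I_DHS`, `I_BG`, `I_Leak`, `I_RestingMET`,
#'   `leak_fraction`, `qc_pass`, `I_Na_recovery`, plus cell metadata
#'   (`genotype`, `position`, `ca_mM`).
#' @export
decompose_recording <- function(rec, window_s = NULL) {
  stopifnot(inherits(rec, "hc_recording"))
  if (rec$mode != "voltage_clamp")
    stop("decomposition requires a voltage-clamp recording")
  perf <- Filter(function(e) e$track == "perfusion", rec$epochs)
  if (!length(perf)) stop("recording has no perfusion epochs")
  if (!length(rec$solutions))
    stop("recording carries no solution table; cannot classify epochs")
  cls <- vapply(perf, function(e) {
    sol <- rec$solutions[[e$label]]
    if (is.null(sol)) NA_character_ else classify_solution(sol)
  }, "")
  first_of <- function(kind) {
    idx <- which(cls == kind)
    if (!length(idx)) return(NULL)
    perf[[idx[1]]]
  }
  ep_na <- first_of("Na")
  ep_nmdg <- first_of("NMDG")
  if (is.null(ep_na)) stop("no Na-containing perfusion epoch found")
  if (is.null(ep_nmdg)) stop("no NMDG perfusion epoch found")
  ep_dhs <- first_of("DHS")

  i_na <- epoch_baseline(rec, ep_na$label, window_s)
  i_nmdg <- epoch_baseline(rec, ep_nmdg$label, window_s)
  i_dhs <- if (!is.null(ep_dhs)) epoch_baseline(rec, ep_dhs$label, window_s)
    else NA_real_

  # recovery check: later Na epochs after the first
  na_idx <- which(cls == "Na")
  i_na_rec <- if (length(na_idx) > 1L)
    epoch_baseline(rec, perf[[na_idx[2]]]$label, window_s) else NA_real_

  i_bg <- i_na - i_nmdg
  i_leak <- if (!is.na(i_dhs)) i_dhs - i_nmdg else NA_real_
  # resting MET = I_Na - I_DHS, computed as I_BG - I_Leak so that the
  # additivity identity holds to the last bit
  i_rmet <- if (!is.na(i_dhs)) i_bg - i_leak else NA_real_
  lf <- if (!is.na(i_leak) && i_bg != 0) i_leak / i_bg else NA_real_

  out <- data.frame(
    I_Na = i_na, I_NMDG = i_nmdg, I_DHS = i_dhs, I_BG = i_bg,
    I_Leak = i_leak, I_RestingMET = i_rmet, leak_fraction = lf,
    qc_pass = abs(i_nmdg) < 20, I_Na_recovery = i_na_rec,
    genotype = rec$meta$genotype, position = rec$meta$position,
    ca_mM = rec$solutions[[ep_na$label]]$ions[["Ca"]])
  class(out) <- c("hc_decomp", class(out))
  out
}

#' Quality-control filter for decomposition results
#'
#' Retains cells whose NMDG baseline magnitude is below 20 pA (strict
#' inequality): larger values indicate a poor seal. The number of rejected
#' cells is reported as a message.
#'
#' @param results a data.frame of stacked [decompose_recording()] rows.
#' @return the retained rows.
#' @export
qc_filter <- function(results) {
  keep <- abs(results$I_NMDG) < 20
  n_rej <- sum(!keep)
  if (n_rej > 0)
    message(n_rej, " of ", nrow(results),
            " cell(s) rejected by the NMDG < 20 pA baseline rule")
  results[keep, , drop = FALSE]
}

#' Mechanically-closed baseline during fluid-jet stimulation
#'
#' During a sinusoidal fluid-jet stimulus the reverse phase of each cycle
#' closes the transducer, so the current there is the MET-closed baseline
#' (leak plus seal). The estimate is the median of the samples falling in a
#' phase window around the reverse-deflection peak of every cycle --
#' equivalent to the per-cycle closed-envelope reading of the trace, but
#' unbiased under zero-mean noise (a raw per-cycle extremum is biased by
#' the noise's expected maximum).
#'
#' @param rec a voltage-clamp [recording()].
#' @param fj_epoch label of the fluid-jet stimulus epoch; by default the
#'   first stimulus epoch whose label starts with `"fj_sine"`.
#' @param freq_hz sine frequency; parsed from a label of the form
#'   `"fj_sine_40Hz"` when `NULL`.
#' @param phase_halfwidth half-width of the phase window around the reverse
#'   peak, as a fraction of a cycle (default 0.1, i.e. +/- 36 degrees).
#' @return the closed baseline, pA.
#' @export
closed_baseline_fj <- function(rec, fj_epoch = NULL, freq_hz = NULL,
                               phase_halfwidth = 0.1) {
  stopifnot(inherits(rec, "hc_recording"))
  stim <- Filter(function(e) e$track == "stimulus", rec$epochs)
  if (is.null(fj_epoch)) {
    hit <- Filter(function(e) startsWith(e$label, "fj_sine"), stim)
    if (!length(hit)) stop("no fluid-jet stimulus epoch in this recording")
    ep <- hit[[1]]
  } else {
    hit <- Filter(function(e) e$label == fj_epoch, stim)
    if (!length(hit)) stop("no stimulus epoch labelled '", fj_epoch, "'")
    ep <- hit[[1]]
  }
  if (is.null(freq_hz)) {
    m <- regmatches(ep$label, regexpr("[0-9.]+(?=Hz)", ep$label, perl = TRUE))
    freq_hz <- if (length(m)) as.numeric(m) else 40
  }
  n_cycles <- floor((ep$t_end - ep$t_start) * freq_hz)
  if (n_cycles < 3) stop("need at least 3 complete stimulus cycles")
  tr <- primary_trace(rec)
  tt <- trace_times(tr)
  sel <- tt >= ep$t_start & tt < ep$t_start + n_cycles / freq_hz
  phase <- ((tt[sel] - ep$t_start) * freq_hz) %% 1
  # x ~ sin(2 pi phase): reverse peak at phase 0.75
  closed <- abs(phase - 0.75) <= phase_halfwidth
  stats::median(tr$samples[sel][closed])
}

#' Leak fraction of the background current, grouped by external Ca2+
#'
#' Computes the per-cell ratio `I_Leak / I_BG` and aggregates it per Ca2+
#' concentration (mean +/- SEM). Ratios are computed per cell and then
#' averaged, matching per-cell error bars; cells with `|I_BG| < min_bg` are
#' excluded with a warning to avoid ratio blow-up.
#'
#' @param results stacked [decompose_recording()] rows with a `ca_mM`
#'   column.
#' @param min_bg minimum background magnitude (pA) for a defined ratio.
#' @return data.frame with columns `ca_mM`, `n`, `mean_ratio`, `sem_ratio`.
#' @export
leak_fraction_by_ca <- function(results, min_bg = 2) {
  ok <- !is.na(results$I_Leak) & !is.na(results$I_BG)
  small <- ok & abs(results$I_BG) < min_bg
  if (any(small))
    warning(sum(small), " cell(s) excluded: |I_BG| < ", min_bg, " pA")
  res <- results[ok & !small, , drop = FALSE]
  if (!nrow(res)) stop("no cells with defined leak fractions")
  ratio <- res$I_Leak / res$I_BG
  agg <- do.call(rbind, lapply(split(ratio, res$ca_mM), function(r)
    data.frame(n = length(r), mean_ratio = mean(r),
               sem_ratio = if (length(r) > 1)
                 stats::sd(r) / sqrt(length(r)) else 0)))
  agg <- cbind(ca_mM = as.numeric(rownames(agg)), agg)
  rownames(agg) <- NULL
  agg[order(agg$ca_mM), , drop = FALSE]
}
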