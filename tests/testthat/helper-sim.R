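# Shared fixtures: configurations and small builders used across the suite.

# default configuration; tau0 = TRUE gives ideal (instantaneous) perfusion
# exchange so noiseless steady baselines are exact
test_config <- function(tau0 = TRUE, seed = 1L) {
  cfg <- default_config(seed)
  if (tau0) cfg$perfusion_tau <- 0
  cfg
}

# flat-baseline voltage-clamp recording with Na / Na+DHS / NMDG epochs at
# given baseline currents (pA), for subtraction arithmetic tests
flat_decomp_recording <- function(i_na, i_dhs, i_nmdg, seg_s = 2,
                                  rate = 1000) {
  n <- seg_s * rate
  sols <- standard_solutions(1.3, 100)
  tr <- trace(c(rep(i_na, n), rep(i_dhs, n), rep(i_nmdg, n)), rate, "pA")
  recording(list(Im = tr),
            list(epoch("144Na", 0, seg_s),
                 epoch("144Na+DHS", seg_s, 2 * seg_s),
                 epoch("144NMDG", 2 * seg_s, 3 * seg_s)),
            default_meta(), "voltage_clamp", -70, sols)
}

# random small recording for round-trip property tests
random_recording <- function(seed) {
  set.seed(seed)
  n <- sample(50:200, 1)
  rate <- sample(c(1000, 5000, 50000), 1)
  dur <- n / rate
  mode <- sample(c("voltage_clamp", "current_clamp"), 1)
  units <- if (mode == "voltage_clamp") "pA" else "mV"
  tr <- trace(stats::rnorm(n, -50, 20), rate, units)
  eps <- list(epoch(sample(c("144Na", "sol_a"), 1), 0, dur / 2),
              epoch("sol_b", dur / 2, dur),
              epoch("stim", dur / 4, dur / 3, "stimulus"))
  sols <- list(solution_spec("144Na", Na = 144, K = 5.8, Ca = 1.3),
               solution_spec("sol_a", NMDG = 144, Ca = runif(1, 0, 35)),
               solution_spec("sol_b", Na = 144, DHS = runif(1, 0, 1000)))
  recording(list(main = tr), eps,
            cell_meta(sample(c("WT", "Tmc1KO", "Lhfpl5KO"), 1),
                      sample(1:14, 1), sample(c("OHC", "IHC"), 1),
                      runif(1), sample(c(TRUE, FALSE), 1)),
            mode, if (mode == "voltage_clamp") -70 else 0, sols)
}
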