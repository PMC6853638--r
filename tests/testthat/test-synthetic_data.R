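# The generative model: configuration defaults, closed-form behaviour of
# the voltage-clamp simulator, unitary gating, and the current-clamp
# integrate-and-fire generator.

test_that("default configuration carries the published calibration", {
  cfg <- default_config()
  expect_equal(cfg$leak$drug_block$DHS$K, 487)
  expect_equal(cfg$leak$drug_block$DHS$h, -0.65)
  expect_equal(cfg$met$drug_block$DHS$K, 15)
  expect_equal(cfg$met$drug_block$DHS$h, -1.10)
  expect_equal(cfg$leak$drug_block$dTC$K, 82)
  expect_equal(cfg$leak$drug_block$amiloride$K, 365)
  expect_equal(cfg$leak$drug_block$Gd$K, 524)
  # unitary map: D60 in the 3 mM regime
  expect_equal(hairclamp:::unitary_current_at(cfg, 0.6, 3), -10.6)
  expect_equal(hairclamp:::unitary_current_at(cfg, 0.05, 35), -4.8)
  # reference cell: -51 pA leak, -7 pA seal at -70 mV in 1.3 mM Ca / 144 Na
  sc <- steady_components(cfg, standard_solutions(1.3)$Na)
  expect_equal(sc[["leak"]], -51, tolerance = 1e-12)
  expect_equal(sc[["seal"]], -7)
  expect_equal(sc[["rest_met"]], 0)
})

test_that("null model produces identically zero current", {
  cfg <- test_config()
  cfg$leak$g_max <- 0
  cfg$seal$g_seal <- 0
  cfg$genotype_effects$WT$met_scale <- 0
  rec <- simulate_voltage_clamp(cfg, decomposition_protocol(), noise = FALSE)
  expect_identical(unique(rec$traces$Im$samples), 0)
})

test_that("noiseless Na->NMDG baseline difference matches the closed form", {
  # independent hand evaluation of the model equations at 0.3 mM Ca2+
  g_max <- 51 / (70 * (5^1.5 / (5^1.5 + 1.3^1.5)))
  L <- g_max * 5^1.5 / (5^1.5 + 0.3^1.5) * 70
  b_dhs_met <- 1 / (1 + (100 / 15)^1.1)        # MET surviving 100 uM DHS
  M <- L * (1 - 0.45) / (0.45 - b_dhs_met)     # calibrated resting MET
  cfg <- test_config()
  rec <- simulate_voltage_clamp(cfg, decomposition_protocol(0.3),
                                noise = FALSE)
  i_na <- epoch_baseline(rec, "144Na")
  i_nmdg <- epoch_baseline(rec, "144NMDG")
  expect_equal(i_na - i_nmdg, -(L + M), tolerance = 1e-10)
})

test_that("fluid-jet envelope equals the Boltzmann excursion", {
  cfg <- test_config()
  rec <- simulate_voltage_clamp(cfg, fj_decomposition_protocol(0.3),
                                noise = FALSE)
  tt <- trace_times(rec$traces$Im)
  stim <- Filter(function(e) e$track == "stimulus", rec$epochs)[[1]]
  sel <- tt >= stim$t_start & tt < stim$t_end
  env <- diff(range(rec$traces$Im$samples[sel]))
  # oracle: A_met * (P(+A) - P(-A)) at -70 mV, P from the resting-anchored
  # Boltzmann with 16 nm slope
  p0 <- hairclamp:::p_open_rest_at(cfg, 0.3)
  pb <- function(x) {
    xh <- 16 * log(1 / p0 - 1)
    1 / (1 + exp((xh - x) / 16))
  }
  a_met <- hairclamp:::met_amplitude_at(cfg, default_meta(), 0.3)
  expect_equal(env, a_met * (pb(400) - pb(-400)), tolerance = 1e-6)
})

test_that("simulation is deterministic given (config, protocol, seed)", {
  cfg <- default_config()
  r1 <- simulate_voltage_clamp(cfg, decomposition_protocol(), seed = 9)
  r2 <- simulate_voltage_clamp(cfg, decomposition_protocol(), seed = 9)
  expect_identical(r1$traces$Im$samples, r2$traces$Im$samples)
  r3 <- simulate_voltage_clamp(cfg, decomposition_protocol(), seed = 10)
  expect_false(identical(r1$traces$Im$samples, r3$traces$Im$samples))

  s1 <- simulate_single_channel(cfg, n_sweeps = 3, seed = 4)
  s2 <- simulate_single_channel(cfg, n_sweeps = 3, seed = 4)
  expect_identical(s1$traces, s2$traces)

  c1 <- simulate_current_clamp(cfg, cc_rest_protocol(2, rate_hz = 5000),
                               seed = 5)
  c2 <- simulate_current_clamp(cfg, cc_rest_protocol(2, rate_hz = 5000),
                               seed = 5)
  expect_identical(c1$traces$Vm$samples, c2$traces$Vm$samples)
})

test_that("leak-only I-V is linear with the configured slope and reversal", {
  cfg <- test_config()
  cfg$genotype_effects$WT$met_scale <- 0
  cfg$seal$g_seal <- 0
  rec <- simulate_voltage_clamp(cfg, ramp_iv_protocol(standard_solutions()$Na),
                                noise = FALSE)
  rmp <- extract_ramp(rec)
  fit <- stats::lm(rmp$current ~ rmp$voltage)
  g_expected <- cfg$leak$g_max * hairclamp:::leak_ca_factor(cfg, 1.3)
  expect_equal(stats::coef(fit)[[2]], g_expected, tolerance = 1e-9)
  expect_equal(-stats::coef(fit)[[1]] / stats::coef(fit)[[2]], 0,
               tolerance = 1e-6)
  expect_lt(max(abs(stats::residuals(fit))), 1e-9)
})

test_that("Tmc1 knockout reproduces its calibrated background current", {
  cfg <- test_config()
  rec <- simulate_voltage_clamp(cfg, decomposition_protocol(1.3),
                                cell_meta("Tmc1KO"), noise = FALSE)
  d <- decompose_recording(rec)
  # KO leak map at the reference position is -18 pA; no resting MET at 1.3
  expect_equal(d$I_BG, -18, tolerance = 1e-9)
  rec_wt <- simulate_voltage_clamp(cfg, decomposition_protocol(1.3),
                                   noise = FALSE)
  expect_equal(d$I_BG / decompose_recording(rec_wt)$I_BG, 18 / 51,
               tolerance = 1e-9)
})

test_that("unitary gating: absorbing closed state and two support points", {
  cfg <- default_config()
  cfg$met$gating_rates$k_open <- 0
  flat <- simulate_single_channel(cfg, n_sweeps = 5, noise = FALSE)
  expect_true(all(vapply(flat$traces, function(tr)
    all(tr$samples == 0), TRUE)))

  cfg2 <- default_config()
  rec <- simulate_single_channel(cfg2, cell_meta(position = 0.6),
                                 n_sweeps = 5, ca_mM = 3, noise = FALSE)
  lv <- sort(unique(unlist(lapply(rec$traces, `[[`, "samples"))))
  expect_true(length(lv) <= 2)
  if (length(lv) == 2) expect_equal(diff(lv), 10.6)
})

test_that("open-state occupancy matches the stationary distribution", {
  cfg <- default_config()
  rec <- simulate_single_channel(cfg, n_sweeps = 20, ca_mM = 3, seed = 3,
                                 noise = FALSE)
  win <- attr(rec, "truth")$step_window
  pooled <- unlist(lapply(rec$traces, function(tr) {
    tt <- trace_times(tr)
    tr$samples[tt >= win[1] & tt < win[2]]
  }))
  occ <- mean(pooled != 0)
  p <- attr(rec, "truth")$p_open
  # binomial error on the effective number of gating events
  n_events <- 20 * 0.06 * cfg$met$gating_rates$k_open
  expect_lt(abs(occ - p), 4 * sqrt(p * (1 - p) / n_events))
})

test_that("current clamp: subthreshold cell stays silent, drive raises Vm", {
  cfg <- default_config()
  rec <- simulate_current_clamp(cfg, cc_rest_protocol(3, rate_hz = 5000),
                                noise = FALSE)
  expect_identical(attr(rec, "truth")$n_spikes, 0L)
  expect_equal(nrow(detect_spikes(rec$traces$Vm)), 0)

  cfgB <- default_config()
  cfgB$ihc$burst$on <- TRUE
  recB <- simulate_current_clamp(cfgB, cc_rest_protocol(3, rate_hz = 5000),
                                 noise = FALSE)
  expect_gt(attr(recB, "truth")$n_spikes, 0)
})

test_that("spike count is non-decreasing with injected current", {
  cfg <- default_config()
  rec <- simulate_current_clamp(cfg, cc_step_protocol(rate_hz = 5000),
                                noise = FALSE)
  fi <- fi_curve(rec)
  expect_true(all(diff(fi$spikes_per_s) >= 0 |
                    fi$spikes_per_s[-1] >= max(fi$spikes_per_s) - 1))
  expect_true(all(fi$spikes_per_s[fi$i_inj <= 0] == 0))
})
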