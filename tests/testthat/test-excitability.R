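# Spike detection, resting-state classification, ramp rheobase and F-I
# analysis of current-clamp recordings.

# helper: ramp analysis for a genotype under the default noiseless ramp
analyze_ramp_injection_of <- function(cfg, genotype) {
  rec <- simulate_current_clamp(cfg, cc_ramp_protocol(rate_hz = 20000),
                                cell_meta(genotype), noise = FALSE)
  analyze_ramp_injection(rec$traces$Vm, rec$traces$Iinj)
}

# a synthetic membrane-potential trace with stereotyped spikes inserted at
# known times: 45 mV rise over 2 ms, fall over 2 ms
spiky_trace <- function(spike_times, duration = 5, rate = 10000,
                        v_base = -60) {
  v <- rep(v_base, duration * rate)
  n_rise <- round(0.002 * rate); n_fall <- round(0.002 * rate)
  wave <- c(seq(v_base, v_base + 45, length.out = n_rise + 1)[-1],
            seq(v_base + 45, v_base - 5, length.out = n_fall + 1)[-1])
  for (ts in spike_times) {
    i0 <- round(ts * rate) + 1
    v[i0:(i0 + length(wave) - 1)] <- wave
  }
  trace(v, rate, "mV")
}

test_that("quiet and subthreshold traces yield no spikes", {
  flat <- trace(rep(-60, 20000), 10000, "mV")
  expect_identical(nrow(detect_spikes(flat)), 0L)
  t <- seq(0, 2, by = 1e-4)
  osc <- trace(-60 + 5 * sin(2 * pi * 2 * t), 10000, "mV")
  expect_identical(nrow(detect_spikes(osc)), 0L)
  expect_error(detect_spikes(trace(rep(-50, 100), 1000, "pA")), "mV")
})

test_that("inserted spikes are each detected once, at insertion time", {
  times <- c(0.5, 1.2, 2.0, 3.3, 4.1)
  sp <- detect_spikes(spiky_trace(times))
  expect_identical(nrow(sp), 5L)
  expect_equal(sp$time, times, tolerance = 2e-4)
  expect_true(all(abs(sp$onset_v - (-60)) < 10))
})

test_that("spike counts match the generator's insertions across seeds", {
  cfg <- default_config()
  for (s in 1:5) {
    rec <- simulate_current_clamp(cfg, cc_step_protocol(rate_hz = 5000),
                                  seed = s)
    sp <- detect_spikes(rec$traces$Vm)
    expect_identical(nrow(sp), attr(rec, "truth")$n_spikes)
  }
})

test_that("state classification splits bursting and silent periods", {
  flat <- trace(rep(-60, 50000), 10000, "mV")
  st <- classify_states(flat, detect_spikes(flat))
  expect_identical(nrow(st), 1L)
  expect_identical(st$state, "non_bursting")
  expect_equal(st$v_mean, -60)
  expect_equal(c(st$t_start, st$t_end), c(0, 5))

  # alternating 2 s bursts / 2 s silence, built by construction
  burst_times <- c(0.2, 0.5, 0.8, 1.2, 1.6,
                   4.2, 4.5, 4.8, 5.2, 5.6)
  vm <- spiky_trace(burst_times, duration = 8)
  st2 <- classify_states(vm, detect_spikes(vm))
  b <- st2[st2$state == "bursting", ]
  expect_identical(nrow(b), 2L)
  expect_lte(max(abs(b$t_start - c(0, 4))), 1)
  expect_lte(max(abs(b$t_end - c(2, 6))), 1)
})

test_that("bursting-state potential is more depolarized than silence", {
  cfg <- default_config()
  cfg$ihc$burst$on <- TRUE
  rec <- simulate_current_clamp(cfg, cc_rest_protocol(10, rate_hz = 5000),
                                seed = 8)
  sp <- detect_spikes(rec$traces$Vm)
  st <- classify_states(rec$traces$Vm, sp)
  expect_true(all(c("bursting", "non_bursting") %in% st$state))
  expect_gt(mean(st$v_mean[st$state == "bursting"]),
            mean(st$v_mean[st$state == "non_bursting"]))
})

test_that("ramp rheobase matches the integrate-and-fire closed form", {
  cfg <- default_config()
  rec <- simulate_current_clamp(cfg, cc_ramp_protocol(rate_hz = 20000),
                                noise = FALSE)
  tr <- attr(rec, "truth")
  a <- analyze_ramp_injection(rec$traces$Vm, rec$traces$Iinj)
  expect_identical(a$status, "ok")
  # g_tot (V_th - V_rest), allowing the integrator lag tau * dI/dt
  lag <- tr$tau_ms / 1000 * (200 / 3)
  expect_lt(abs(a$i_min - tr$i_min_analytic), lag + 0.5)
  expect_equal(a$v_threshold, tr$V_th, tolerance = 0.5)
})

test_that("a 13 mV resting shift moves the rheobase by g times 13", {
  cfg <- default_config()
  a_wt <- analyze_ramp_injection_of(cfg, "WT")
  a_ko <- analyze_ramp_injection_of(cfg, "Tmc1KO")
  expect_equal(a_ko$i_min - a_wt$i_min, cfg$ihc$g_tot_nS * 13,
               tolerance = 0.5)
  # threshold is a voltage criterion: identical across genotypes
  expect_equal(a_ko$v_threshold, a_wt$v_threshold, tolerance = 0.5)
})

test_that("threshold is independent of the injected-current slope", {
  cfg <- default_config()
  fast <- simulate_current_clamp(cfg, cc_ramp_protocol(ramp_s = 1.5,
                                                       rate_hz = 20000),
                                 noise = FALSE)
  slow <- simulate_current_clamp(cfg, cc_ramp_protocol(ramp_s = 6,
                                                       rate_hz = 20000),
                                 noise = FALSE)
  a_f <- analyze_ramp_injection(fast$traces$Vm, fast$traces$Iinj)
  a_s <- analyze_ramp_injection(slow$traces$Vm, slow$traces$Iinj)
  expect_equal(a_f$v_threshold, a_s$v_threshold, tolerance = 0.5)
})

test_that("a hyperpolarized cell with a capped ramp never fires", {
  cfg <- default_config()
  rec <- simulate_current_clamp(cfg, cc_ramp_protocol(from = -100, to = 20,
                                                      rate_hz = 10000),
                                cell_meta("Tmc1KO"), noise = FALSE)
  a <- analyze_ramp_injection(rec$traces$Vm, rec$traces$Iinj)
  expect_identical(a$status, "no_spikes")
  expect_true(is.na(a$i_min) && is.na(a$v_threshold))
})

test_that("F-I curves shift right for the hyperpolarized genotype", {
  cfg <- default_config()
  fi_wt <- fi_curve(simulate_current_clamp(cfg,
                                           cc_step_protocol(rate_hz = 5000),
                                           noise = FALSE))
  fi_ko <- fi_curve(simulate_current_clamp(cfg,
                                           cc_step_protocol(rate_hz = 5000),
                                           cell_meta("Tmc1KO"),
                                           noise = FALSE))
  expect_true(all(fi_wt$spikes_per_s[fi_wt$i_inj < 0] == 0))
  # knockout needs more current for the same rate ...
  expect_gt(min(fi_wt$i_inj[fi_wt$spikes_per_s > 0]),
            -Inf)
  expect_lt(min(fi_wt$i_inj[fi_wt$spikes_per_s > 0]),
            min(fi_ko$i_inj[fi_ko$spikes_per_s > 0]))
  # ... but both converge to the refractory-limited plateau
  expect_equal(max(fi_wt$spikes_per_s), max(fi_ko$spikes_per_s),
               tolerance = 0.15)
})

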