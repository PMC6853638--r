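# Background-current decomposition: subtraction arithmetic, QC rule,
# mechanically-closed baseline, and leak-fraction aggregation.

# one-row decomposition result with a given NMDG baseline
flat_to_row <- function(i_nmdg)
  decompose_recording(flat_decomp_recording(-50, -40, i_nmdg))

test_that("noiseless decomposition recovers the generator ground truth", {
  # a wild-type cell configured with -51 pA leak and -20 pA resting MET:
  # saturating DHS in the blocker segment makes the split exact
  cfg <- test_config()
  a_ref <- hairclamp:::met_amplitude_at(cfg, default_meta(), 1.3)
  cfg$met$p_open_rest$p[cfg$met$p_open_rest$ca_mM == 1.3] <- 20 / a_ref
  rec <- simulate_voltage_clamp(cfg,
                                decomposition_protocol(1.3, dhs_uM = 1e6),
                                noise = FALSE)
  d <- decompose_recording(rec)
  expect_equal(d$I_BG, -71, tolerance = 1e-4)
  expect_equal(d$I_Leak, -51, tolerance = 1e-4)
  expect_equal(d$I_RestingMET, -20, tolerance = 1e-4)
  expect_identical(d$I_BG, d$I_Leak + d$I_RestingMET)
  expect_true(d$qc_pass)
})

test_that("subtraction of narrated baselines gives the printed components", {
  rec <- flat_decomp_recording(i_na = -98, i_dhs = -55, i_nmdg = 0)
  d <- decompose_recording(rec)
  expect_identical(d$I_RestingMET, -43)
  expect_identical(d$I_Leak, -55)
  expect_identical(d$I_BG, -98)
})

test_that("identical Na and NMDG baselines give zero background current", {
  rec <- flat_decomp_recording(-12, -12, -12)
  expect_identical(decompose_recording(rec)$I_BG, 0)
})

test_that("decomposition errors name the missing epoch", {
  sols <- standard_solutions()
  rec <- recording(trace(rep(-50, 2000), 1000, "pA"),
                   list(epoch("144Na", 0, 2)), default_meta(),
                   "voltage_clamp", -70, sols)
  expect_error(decompose_recording(rec), "NMDG")
  rec2 <- recording(trace(rep(-7, 2000), 1000, "pA"),
                    list(epoch("144NMDG", 0, 2)), default_meta(),
                    "voltage_clamp", -70, sols)
  expect_error(decompose_recording(rec2), "Na-containing")
})

test_that("the NMDG < 20 pA quality rule is applied strictly", {
  res <- rbind(
    transform(flat_to_row(-7), cell = 1),    # wild-type cohort value
    transform(flat_to_row(-25), cell = 2),
    transform(flat_to_row(-20), cell = 3))   # boundary: rejected
  expect_message(kept <- qc_filter(res), "2 of 3")
  expect_identical(kept$cell, 1)
})

test_that("additivity holds to machine precision on noisy decompositions", {
  cfg <- default_config()
  for (s in 1:20) {
    d <- decompose_recording(
      simulate_voltage_clamp(cfg, decomposition_protocol(1.3), seed = s))
    expect_identical(d$I_BG, d$I_Leak + d$I_RestingMET)
  }
})

test_that("decomposed components are unbiased under recording noise", {
  cfg <- default_config()
  cfg$perfusion_tau <- 0   # isolate noise from exchange transients
  noiseless <- decompose_recording(
    simulate_voltage_clamp(cfg, decomposition_protocol(0.3), noise = FALSE))
  reps <- do.call(rbind, lapply(1:200, function(s)
    decompose_recording(
      simulate_voltage_clamp(cfg, decomposition_protocol(0.3), seed = s))))
  for (col in c("I_Na", "I_NMDG", "I_BG", "I_Leak", "I_RestingMET")) {
    sem <- stats::sd(reps[[col]]) / sqrt(nrow(reps))
    expect_lt(abs(mean(reps[[col]]) - noiseless[[col]]), 2 * sem + 1e-9)
  }
})

test_that("fluid-jet closed baseline reads the leak + seal level", {
  cfg <- test_config()
  rec <- simulate_voltage_clamp(cfg, fj_decomposition_protocol(0.3),
                                noise = FALSE)
  truth <- steady_components(cfg, standard_solutions(0.3)$Na)
  expect_equal(closed_baseline_fj(rec),
               truth[["leak"]] + truth[["seal"]], tolerance = 1e-6)

  # no MET modulation (double knockout): envelope equals the plain baseline
  recK <- simulate_voltage_clamp(cfg, fj_decomposition_protocol(0.3),
                                 cell_meta("Tmc1Tmc2DKO"), noise = FALSE)
  expect_equal(closed_baseline_fj(recK),
               epoch_baseline(recK, "144Na"), tolerance = 1e-9)

  expect_error(closed_baseline_fj(
    simulate_voltage_clamp(cfg, decomposition_protocol(), noise = FALSE)),
    "no fluid-jet")
})

test_that("fluid-jet closed baseline is unbiased over noisy replicates", {
  cfg <- default_config()
  cfg$perfusion_tau <- 0
  short <- protocol(list(proto_seg("144Na", 1),
                         proto_seg("144Na", 3, stim_fj_sine(40, 400))),
                    standard_solutions(0.3), "voltage_clamp", 1000)
  noiseless <- closed_baseline_fj(
    simulate_voltage_clamp(cfg, short, noise = FALSE))
  est <- vapply(1:200, function(s)
    closed_baseline_fj(simulate_voltage_clamp(cfg, short, seed = s)), 0)
  sem <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - noiseless), 2 * sem + 1e-9)
})

test_that("leak fraction aggregates per concentration with exclusions", {
  res <- data.frame(I_Leak = c(-50, -50, -1, -40), I_BG = c(-50, -50, -1, -80),
                    I_NMDG = -5, ca_mM = c(1.3, 1.3, 1.3, 0.3))
  expect_warning(tab <- leak_fraction_by_ca(res), "excluded")
  r13 <- tab[tab$ca_mM == 1.3, ]
  expect_identical(r13$mean_ratio, 1)
  expect_identical(r13$sem_ratio, 0)
  expect_identical(r13$n, 2L)
  expect_equal(tab[tab$ca_mM == 0.3, "mean_ratio"], 0.5)
})

test_that("simulated cohorts recover the published leak fractions", {
  cfg <- default_config()
  run_cohort <- function(ca, seeds) do.call(rbind, lapply(seeds, function(s)
    decompose_recording(
      simulate_voltage_clamp(cfg, decomposition_protocol(ca), seed = s))))
  tab13 <- leak_fraction_by_ca(run_cohort(1.3, 1:10))
  expect_equal(tab13$mean_ratio, 1.00, tolerance = 0.02)
  tab03 <- leak_fraction_by_ca(run_cohort(0.3, 11:20))
  expect_equal(tab03$mean_ratio, 0.45, tolerance = 0.05)
})
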