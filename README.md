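# hairclamp

Simulation and analysis of whole-cell patch-clamp recordings from cochlear
hair cells, built around one scientific question: outer and inner hair
cells carry a standing **background leak conductance** that is distinct
from the mechano-electrical transducer (MET) channel, is blocked by
impermeant-cation (NMDG⁺) substitution and by high external Ca²⁺, is
antagonized by MET-channel blockers at much higher doses, is graded along
the tonotopic (apex→base) axis, and sets the excitability of inner hair
cells. The package provides, as tested and reusable code, the full
inference chain that turns raw perfusion-annotated current traces into
those claims — together with a generative model of the recordings so that
every stage can be validated against known ground truth without any
laboratory data.

It is intended for cellular electrophysiologists and methods developers
who want a reference implementation of these analyses, a simulator to
benchmark them on, or a starting point for their own recordings (a
plain-text container format with a JSON sidecar is included; an import
shim for amplifier-vendor formats is a documented extension point).

## The analyses

**Current decomposition by ionic substitution.** With baselines read as
steady-state medians of perfusion epochs,

    I_BG   = I_Na  − I_NMDG      (background current, seal leak excluded)
    I_Leak = I_DHS − I_NMDG      (MET-independent leak)
    I_Resting-MET = I_Na − I_DHS (DHS-sensitive resting MET current)

so that `I_BG = I_Leak + I_Resting-MET` is an arithmetic identity.
Cells are kept only when the NMDG baseline is below 20 pA (seal quality).

**Hill dose-inhibition fitting.** Normalized responses follow
`I_X / I_max = X^h / (K^h + X^h)` with `K` the IC50 and `h < 0` the Hill
slope; fits run on `log K` with percentile-bootstrap confidence intervals
resampled over cells. A plateau variant handles Ca²⁺-substitution series
where the MET current saturates instead of vanishing.

**Permeability ratios.** Reversal potentials come from a linear fit to
the inward limb of −120→+80 mV ramp I-V curves after per-cell subtraction
of the NMDG ramp; relative permeabilities use the bi-ionic GHK forms

    P_X/P_Cs = [Cs]ᵢ e^u / [X]ₒ                                  (monovalent)
    P_X/P_Cs = γ_Cs [Cs]ᵢ e^u (e^u + 1) / (4 γ_X [X]ₒ),  u = E_rev F/RT

with activity coefficients γ_Cs = 0.70, γ_Ca = 0.4657, γ_Mg = 0.5271 and
T = 298.15 K.

**Unitary currents.** 100 kHz probe-step sweeps are screened for obvious
single-channel events (excursion and bimodality rules), pooled, and fitted
with a two-component Gaussian mixture by expectation–maximization; the
unitary current is the separation of the closed and open peaks.

**Excitability.** Spikes are detected by a dV/dt-threshold criterion;
resting activity is split into bursting/non-bursting states; ramp
injections yield the firing threshold and the minimum injected current
(rheobase); step families yield F-I curves.

**Tonotopy.** Per-cell measures are aggregated over the canonical
positions D05–D80 (fractional distance from the apex) and gradients are
tested by one-way ANOVA plus a linear trend regression.

## Worked example

```r
library(hairclamp)
cfg <- default_config(seed = 1)

# simulate a wild-type cohort under Na -> Na+DHS -> NMDG perfusion,
# decompose each cell, and aggregate the leak fraction
cells <- do.call(rbind, lapply(1:5, function(i)
  decompose_recording(simulate_voltage_clamp(
    cfg, decomposition_protocol(ca_mM = 1.3), seed = i))))
leak_fraction_by_ca(qc_filter(cells))
#>   ca_mM n mean_ratio    sem_ratio
#> 1   1.3 5   1.001012 0.0008357578

# Hill fit of a simulated DHS dose-inhibition table for the MET current
tab <- simulate_dose_table(cfg$met$drug_block$DHS,
                           doses = 10^seq(0, 3, length.out = 8),
                           n_cells = 8, cv = 0.05, seed = 2)
fit_hill(tab, "I_MET", n_boot = 500, seed = 1)
#> <hc_hillfit> I_MET: IC50 = 15.23, h = -1.08  [K 95% CI 14.57..15.88, 500 boot]

# unitary MET current at position D60 in 3 mM Ca2+
rec <- simulate_single_channel(cfg, cell_meta(position = 0.6),
                               n_sweeps = 12, ca_mM = 3, seed = 5)
unitary_from_recording(rec, seed = 1)
#> <hc_mixfit> i_unit = -10.4 pA (closed -0.00416 +/- 0.8, open -10.4 +/- 0.8,
#>             w_open = 0.343)
```

The first block shows that, at 1.3 mM external Ca²⁺, essentially the whole
background current of the simulated wild-type cell is MET-independent leak
(ratio ≈ 1.00); the Hill fit recovers the generating IC50 of 15 μM and
slope −1.10 within the bootstrap interval; the dual-peak fit recovers the
configured −10.6 pA unitary current to within its Monte-Carlo scatter.

## Vignette

`vignettes/hairclamp-methods.Rmd` documents the generative model and its
calibration, every tunable parameter with units and defaults, the
numerical choices inside the estimators, and what the synthetic-data
tests do and do not demonstrate about laboratory recordings.
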