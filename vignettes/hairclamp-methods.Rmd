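---
title: "hairclamp: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hairclamp: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model of hair-cell membrane currents, how it is calibrated, the estimators
built on top of it, and the numerical decisions inside each one. The
worked numbers quoted here are the ones the test suite and
`scripts/acceptance.R` themselves compute; nothing is asserted that the
code does not re-derive.

## 1. The generative model

A voltage-clamped hair cell at membrane potential $V$ (mV) in an external
solution $S$ produces, in this model,

$$I(t) = I_\mathrm{leak} + I_\mathrm{MET} + I_\mathrm{seal} + \varepsilon(t)$$

with all currents in pA and inward current negative.

**Leak.** The background leak conductance is ohmic with reversal near
0 mV (it is carried non-selectively by external cations):

$$I_\mathrm{leak} = g_\mathrm{max}\, s(g, D)\, f_\mathrm{cat}(S)\,
  B_\mathrm{Ca}([\mathrm{Ca}]_o)\, \prod_d B_d(X_d)\; (V - E_\mathrm{rev})$$

* $g_\mathrm{max}$ (nS) is calibrated so the reference cell carries
  −51 pA of leak at −70 mV in 144 mM Na⁺ / 1.3 mM Ca²⁺ (the
  apical-middle wild-type cohort mean).
* $s(g, D)$ is the genotype- and position-dependent scale: absolute
  tonotopic current maps over the canonical positions D05–D80, linearly
  interpolated, divided by the 51 pA reference. The wild-type map is
  −23 / −63 / −67 / −84 pA at D05/D20/D40/D60; D80 (−101 pA) is a linear
  extrapolation of the D40–D60 segment, which the source data do not
  constrain. The *Tmc1*-knockout map (−18 / −18 / −10 / −5 pA) loses the
  gradient and inverts it; *Lhfpl5*-knockouts use 0.2 × the wild-type
  curve; bundle removal multiplies the leak by 0.2 and silences the MET
  terms.
* $f_\mathrm{cat}(S) = ([\mathrm{Na}] + [\mathrm{Li}] + [\mathrm{Cs}])/144$
  is the permeant-cation fraction. NMDG⁺ carries nothing, so the standard
  144 mM NMDG solution reduces the model current to the seal leak alone —
  the operational meaning of the NMDG baseline. K⁺ (5.8 mM in every
  solution) is deliberately excluded from the permeant set so that this
  holds exactly; at 4% of the reference drive its omission is far below
  the noise floor.
* $B_\mathrm{Ca}$ is a Hill block term with $K = 5$ mM and exponent 1.5.
  The source observations constrain only two features — the leak is
  nearly intact at 1.3 mM Ca²⁺ and suppressed to knockout-like levels by
  35 mM — and this pair $(K, h)$ satisfies both ($B_\mathrm{Ca}(1.3) =
  0.88$, $B_\mathrm{Ca}(35) = 0.05$); the functional form between those
  anchors is a modeling choice.
* $B_d$ are Hill block terms for the five tabled blockers. The
  configuration stores the fitted dose-inhibition pairs for both
  conductances (MET: DHS 15 μM/−1.10, dTC 6/−0.47, amiloride 46/−1.36,
  Gd³⁺ 66/−0.48, La³⁺ 259/−1.06; leak: DHS 487/−0.65, dTC 82/−2.80,
  amiloride 365/−1.67, Gd³⁺ 524/−2.49, La³⁺ 531/−5.67 — two values, 524
  and 541 μM, are reported for the Gd³⁺/leak pair and 524 is the one
  stored). **By default the trace simulator applies only the MET table.**
  The fitted leak curve for DHS, extrapolated to the 100 μM working
  concentration, would predict ~26% leak block there; the direct
  observation is that the working concentration leaves the baseline
  untouched, and the leak/background ratio of 1.00 at 1.3 mM Ca²⁺ is only
  consistent with the observation, not with the extrapolation. The
  simulator follows the measurement; setting
  `leak$apply_drug_block = TRUE` switches the fitted curve on for users
  who want Fig-5-style full dose series in the trace domain.

**MET.** The transducer population contributes

$$I_\mathrm{MET} = A_\mathrm{MET}(D, \text{regime})\, P_o(x)\,
  \prod_d B_d(X_d)\, f_\mathrm{cat}(S)\, V/70$$

where $A_\mathrm{MET}$ is the saturating macroscopic MET magnitude at
−70 mV from tonotopic maps (1.3 mM regime −505/−780/−872/−939 pA at
D05/D20/D40/D80 with D60 interpolated; a flatter 35 mM regime; a
gradient-inverted knockout map), and $P_o$ is a Boltzmann in bundle
displacement $x$ with 16 nm slope, anchored so that $P_o(0)$ equals the
resting open probability for the current Ca²⁺ concentration.

The resting open probability is the model's second calibrated quantity.
The decomposition protocol *measures* the leak fraction
$(L + B_M M)/(L + M)$, where $B_M = 0.110$ is the fraction of resting MET
current surviving 100 μM DHS under the MET Hill table. The knots of
$p_\mathrm{rest}([\mathrm{Ca}]_o)$ are therefore solved so that the
*measured* ratio equals the reported values 0.29 / 0.45 / 0.47 / 1.00 at
0.1 / 0.3 / 0.5 / 1.3 mM, with concentrations ≥ 1.3 mM treated as
saturated ($p_\mathrm{rest} = 0$; the reported 0.96 at 3.0 mM sits within
its error of saturation). Between knots the interpolation is linear in
$\log_{10}[\mathrm{Ca}]_o$.

One consequence deserves emphasis: with resting MET absent at 1.3 mM
Ca²⁺, the simulated wild-type background current at 1.3 mM equals the
leak, about −51 pA. Published cohort means from different cell groups
(−71 pA background in one cohort, −51 pA leak and a leak fraction of 1.00
in another) are not jointly consistent under per-cell arithmetic, and
this generator resolves the conflict in favour of the ratio calibration,
which is the quantity its pipeline actually recovers.

**Unitary channels.** Single-channel sweeps use two-state Markov gating
(closed ↔ open, default $k_o = 500\,/\mathrm{s}$,
$k_c = 1000\,/\mathrm{s}$, so stationary $P_o = 1/3$ during the step) at
100 kHz, with open-channel current from the unitary tonotopic map: 3 mM
Ca²⁺ regime −7.0 / −7.9 / −10.6 pA at D05/D20/D60 (D40, D80 filled by the
same interpolation rule). The 35 mM map is stored flat at −4.8 pA — high
Ca²⁺ abolishes the gradient, and the per-position readings −4.7/−4.8/−4.9
scatter within their SEMs. A 2% cell-to-cell scatter on the amplitude
(`met$i_unit_cv`) gives cohorts a biological variance component so group
SEMs and gradient statistics are meaningful. Sweeps are generated
baseline-subtracted (closed level 0); the analysis is offset-invariant
regardless.

**Seal and noise.** A 0.1 nS ohmic seal leak (−7 pA at −70 mV) stands for
the imperfect pipette seal; it is what the NMDG baseline and the
20 pA quality-control rule act on. Recording noise is white Gaussian with
2 pA rms at 1 kHz, scaled by $\sqrt{\text{rate}/1\,\mathrm{kHz}}$ at
other sampling rates; unitary sweeps instead use a post-filter rms of
0.8 pA, matching the visual noise of published 100 kHz sweeps after
display filtering. Perfusion switches mix exponentially with
$\tau = 2$ s, producing realistic exchange transients; setting
`perfusion_tau = 0` gives ideal instantaneous exchange, which the
noiseless exactness tests use.

**Inner-hair-cell spiking.** Current-clamp traces come from a leaky
integrate-and-fire membrane, $C\,\dot V = -g_\mathrm{tot}(V - V_r) +
I_\mathrm{inj}$, with $C = 10$ pF, $g_\mathrm{tot} = 1.5$ nS, threshold
−47 mV, resting potential −60 mV (wild type) or −73 mV (*Tmc1* knockout),
a stereotyped inserted spike waveform (2 ms rise to 45 mV above
threshold, 2 ms fall to the −65 mV reset) and a 70 ms absolute refractory
period during which the membrane is shunted at threshold. These defaults
reproduce the reported 13 mV resting-potential gap, the common −47 mV
threshold, a rheobase difference of $g\,\Delta V_r \approx 20$ pA and an
F-I plateau near 14 spikes/s. The generator is phenomenological — it
exists to exercise spike detection, threshold and F-I code, not to model
IHC conductances (no Kv families, no synaptic machinery); an optional
slow sinusoidal drive (0.4 Hz, 14 mV) emulates spontaneous bursting.

### The reference cell

`default_meta()` places the reference wild-type P6 outer hair cell at
D = 0.155: the interpolated position where the wild-type leak map crosses
the −51 pA apical-middle cohort mean. This makes tonotopic scaling exactly
1 for the cohorts that calibrate the model, while cells placed at the
canonical D05–D80 positions reproduce the printed group means exactly in
noiseless simulation.

## 2. Estimators and their numerical choices

**Baselines.** `epoch_baseline()` takes the median of the final 20% of a
perfusion epoch (minimum 0.5 s) — the steady state after exchange. The
median resists residual MET events and brief artefacts; the source
analyses never state their read-off rule, so this is the package's
documented choice. Epochs are half-open $[t_0, t_1)$ in seconds from
recording start.

**Smoothing.** `binomial_smooth()` convolves with (¼, ½, ¼) per pass,
edges replicated; 20 passes reproduce the customary "Binomial 20" display
filter. Replicate padding is the package's choice of edge rule (the
original display tool leaves it undocumented); constants are preserved
exactly and interior samples match the order-$2p$ binomial kernel.

**Decomposition.** When wash-in/wash-out produces several Na⁺ epochs, the
*first* defines $I_{Na}$ and later ones are reported as recovery checks.
`I_RestingMET` is computed as `I_BG − I_Leak` so the additivity identity
holds to the last bit (mathematically it equals $I_{Na} − I_{DHS}$).
Ratios are computed per cell and then averaged — matching per-cell error
bars — and cells with $|I_{BG}| < 2$ pA are excluded, not clipped, to
avoid ratio blow-up. The quality rule $|I_{NMDG}| < 20$ pA is strict at
the boundary. `closed_baseline_fj()` reads the MET-closed level during
sinusoidal fluid-jet stimulation as the median of samples within ±36° of
the reverse-deflection phase peak: on noiseless traces this equals the
per-cycle closed-envelope reading, and unlike a raw per-cycle extremum it
is unbiased under noise (an extremum estimator inherits the expected
maximum of the noise).

**Hill fits.** `fit_hill()` optimizes on $\log K$ (positivity by
construction) with the slope unconstrained, initialized at $h = -1$ and
$K$ at the dose whose mean response is nearest 0.5, with a small fallback
grid of starts; failures carry the initializations tried. Zero doses use
the analytic limit of the Hill function and serve as within-cell
normalization controls; tables without them are assumed pre-normalized.
Confidence intervals are percentile bootstrap over *cells* (default 500
resamples, seeded), because points within a cell are correlated.
`fit_ca_block()` adds a plateau term $p + (1-p)\,\mathrm{hill}$ for the
MET component, bounded to $[0, 0.95]$.

**Reversal potentials.** `estimate_reversal()` fits a line to the inward
limb and reports its zero crossing. The limb is delimited by a *voltage*
cutoff — the first voltage where the running-mean-smoothed current comes
within 2 noise-rms of zero — rather than by each sample's own current:
conditioning the selection on the outcome variable truncates the noise
distribution and biases the crossing by several tenths of a mV, which the
voltage-cutoff rule avoids (measured bias < 0.01 mV at 2 pA rms). A
never-crossing inward ramp is extrapolated; an everywhere-outward ramp,
fewer than 10 inward samples, or a non-positive inward slope are errors.
The divalent permeability equation is implemented with
$\exp(E_\mathrm{rev}F/RT)$ in both factors — some printed versions drop
the $F$ inside the bracket, which dimensional analysis forbids. Internal
Cs⁺ defaults to 150 mM for permeability work (the concentration quoted
with that experiment) with 140 mM available where the general-recording
pipette is meant.

**Dual-peak fits.** `fit_two_gaussians()` runs expectation–maximization
on raw samples (≥ 1000 required; binning is for diagnostics only), with
quantile-based initial means plus five seeded random restarts, keeping
the best likelihood. Component σ is floored at $10^{-3}$ pA to keep the
likelihood bounded. Fits are rejected as degenerate when the means fall
within 0.5 pA or a component weight falls below 2% (the classic
EM collapse onto a handful of points). Sweep selection demands a
4 × rms inward excursion of the display-filtered sweep — filtering first
matters, because the raw minimum of thousands of noise samples alone
approaches 4 rms — plus an open-level occupancy between 5% and 95%
(the bimodality screen), and excludes sweeps where a 3-component mixture
beats the 2-component fit by more than 10 BIC (double openings).

**Spike detection.** A spike is an upward crossing of 10 mV/ms followed
within 5 ms by a peak ≥ 20 mV above the pre-spike baseline (median of the
−20…−5 ms window), with a 3 ms lockout. Burst classification uses 1 s
windows with ≥ 2 spikes; state-wise mean potentials blank ±10 ms around
each spike. All thresholds are arguments: the source reports spikes,
thresholds and states without defining detectors, so these are documented
heuristics. Under a current ramp the recovered rheobase carries the
integrator lag $\tau\,\mathrm{d}I/\mathrm{d}t$ (≈ 0.4 pA at the standard
3 s ramp), which the tests account for explicitly.

**Tonotopy.** Positions snap to the canonical grid within ±0.05; off-grid
cells keep their own D for the trend regression but stay out of the
canonical-group ANOVA. The gradient test pairs a one-way ANOVA over
positions (the group-difference test reported with such data) with a
per-cell linear regression on D whose slope, SE and t-test give the trend
statistic. Liquid junction potentials (+4 mV in Na⁺, −6 mV in NMDG⁺ with
the Cs⁺ pipette) are stored in the configuration and *not* applied,
matching the uncorrected convention of the source recordings.

## 3. Problem sizes

The test suite and acceptance script run entirely on simulated data at
sizes chosen to give each estimator comfortable statistical resolution:
dose-inhibition recovery uses 8 log-spaced doses × 8 cells × 5%
multiplicative noise over 50–200 seeded replicates; the decomposition
cohorts use 10–32 cells of 28 s traces at 1 kHz; reversal calibration
uses 100 noisy 2000-point ramps; unitary recovery uses 50 replicates of
8 × 40 ms sweeps at 100 kHz; current-clamp analyses run at 5–20 kHz.
These sizes are the package's own choices and can be scaled up freely.

## 4. What the synthetic tests do and do not show

Passing the suite demonstrates that every estimator recovers the
generative model's ground truth at the designed noise levels, that the
subtraction identities and QC rules behave exactly as specified, and that
the full simulate → decompose → aggregate pipeline reproduces its own
calibration (leak fraction 1.00 at 1.3 mM Ca²⁺; IC50s of 15/487/82/365 μM
for the four recovery designs; −10.6 pA at D60).

It does **not** demonstrate performance on laboratory data. Real
recordings contain series-resistance and capacitive transients (neither
modeled nor corrected), rundown and drift, correlated (non-white) noise,
perfusion artefacts beyond first-order mixing, multi-channel and subtype
heterogeneity in unitary sweeps, and genuine biological spread far beyond
the 2% amplitude scatter modeled here. The IHC generator in particular is
an integrate-and-fire stand-in: its F-I ceiling comes from a refractory
constant, not from the Kv conductances that shape real IHC spikes.
Estimator behaviour under those conditions must be validated against real
traces; the container format and the config-exposed thresholds exist to
make that straightforward.
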