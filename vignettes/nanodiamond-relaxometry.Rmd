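---
title: "Modelling a Cu(II)/H2O2 Fenton-like reaction for nanodiamond relaxometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a Cu(II)/H2O2 Fenton-like reaction for nanodiamond relaxometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndfenton)
```

## The measurement this package models

Nitrogen-vacancy (NV) centers in fluorescent nanodiamonds can be polarized
into their bright spin state with a green laser pulse; magnetic noise from
nearby unpaired electron spins (paramagnetic Cu²⁺, hydroxyl radicals,
superoxide) shortens the time T1 over which that polarization survives in
the dark. Sweeping the dark time τ between a 5 µs polarization pulse and a
readout pulse, and integrating the readout fluorescence in a detection
window, yields a relaxation curve that is well described by a bi-exponential,

$$PL(\tau) = I_\infty + C_a e^{-\tau/T_a} + C_b e^{-\tau/T_b},
\qquad T_a \le T_b,$$

where the two components stand for fast- and slow-relaxing sub-ensembles of
the several hundred NV centers in one particle; the long component $T_b$ is
"the T1" reported everywhere in this package, because it is the part that
tracks the surrounding paramagnetic concentration. One acquisition repeats
the τ-sweep 10,000 times (≈10 min); fitting overlapping blocks of
repetitions (2500-repetition windows advanced by 100) time-resolves T1
within a single acquisition.

During a Cu(II)/H₂O₂ Fenton-like reaction the copper(II) concentration drops
as copper cycles through Cu⁺/Cu³⁺ and peroxide decomposes, so T1 — initially
depressed far below the ultrapure-water baseline — partially recovers.
Benchtop channels corroborate each piece: UV–Vis absorbance of the Cu²⁺ d–d
band at 800 nm, terephthalate trapping of hydroxyl radicals read out as HTA
fluorescence at 420 nm, the 876 cm⁻¹ O–O stretch of H₂O₂ in Raman, and a
dissolved-oxygen probe.

`ndfenton` builds a single synthetic world in which all five channels are
generated from one seeded kinetic simulation, and implements the complete
analysis chain used on the real data. Green tests establish that the
analysis chain is correct *on data satisfying the generators' assumptions*;
they cannot certify instrument-specific effects the generators omit (see
"Limitations").

## The kinetic model

Mass-action kinetics over twelve species with eight elementary steps:

| step | reaction | constant |
|------|----------|----------|
| R1 | Cu²⁺ + H₂O₂ → Cu³⁺ + OH• + OH⁻ | `k1` |
| R2 | Cu²⁺ + H₂O₂ → Cu⁺ + O₂•⁻ + 2H⁺ | `k2` |
| R3 | Cu²⁺ + O₂•⁻ → Cu⁺ + O₂ | `k3` |
| R4 | OH• + H₂O₂ → HO₂• + H₂O | `k4` |
| R5 | HO₂• + HO₂• → H₂O₂ + O₂ | `k5` |
| R6 | OH• + OH• → H₂O₂ | `k6` |
| R7 | Cu⁺ + H₂O₂ → Cu²⁺ + OH• + OH⁻ | `k7` |
| Rtrap | OH• + TH²⁻ → HTA | `k_trap` |

Every step conserves total copper; the constructor verifies this and the
test suite asserts conservation to 10⁻⁶ relative along whole trajectories.

**Why R7 exists.** The source experiments report, for the same default
scenario (1 mM Cu²⁺, 10 mM H₂O₂, 20 min), a 0.2 mM copper decrease *and*
14 mg/L (437.5 µM) of liberated O₂. If Cu⁺ and Cu³⁺ were terminal sinks,
every O₂ molecule would cost two Cu²⁺ (either via R2+R3 or via R1+R4+R5),
capping liberated O₂ at 0.1 mM ≈ 3.2 mg/L. The two observables are only
jointly reachable if copper acts catalytically, so the model closes the
textbook Fenton-like cycle with R7 (peroxide re-oxidation of Cu⁺). With R7
the net chemistry is a copper-catalysed peroxide disproportionation
2 H₂O₂ → 2 H₂O + O₂, with a modest standing inventory of Cu⁺ plus a slow
irreversible leak into Cu³⁺ accounting for the observed Cu²⁺ decrease.

**Rate constants are effective, not literature values.** No rate constants
are reported for this system, so the defaults are free parameters of the
synthetic world. Two considerations fixed them once (script in
`data-raw/tune-rate-constants.R`), and they have not been revisited:

* the radical scales (`k3 = 1e6`, `k4 = 1e4`, `k5 = 1e6`, `k6 = 1e9`
  M⁻¹s⁻¹) keep every relaxation time of the network slower than ~1 ms, so
  the system is integrable by an explicit adaptive stepper in well under a
  second — real radiolysis constants (10⁹–10¹⁰ M⁻¹s⁻¹) would demand a stiff
  implicit solver without changing any observable this package asserts,
  because only flux ratios matter for the headline numbers;
* `k1`, `k2` and `k_trap` were then solved so the default 20-minute scenario
  reproduces the three headline observables exactly: 0.2 mM Cu²⁺ decrease,
  0.9 µM trapped hydroxyl radical, 14 mg/L liberated O₂
  (`k1 = 1.434e-2`, `k2 = 2.070e-2`, `k_trap = 1.860` M⁻¹s⁻¹, `k7 = 0.6`
  fixed to set the Cu⁺ inventory share).

The low effective `k_trap` encodes, in one number, that the dosimeter
captures only a small fraction of the hydroxyl flux in this model's default
scenario; the generator also honours the trap-dominant regime (large
`k_trap`·[TH²⁻]), where cumulative HTA equals cumulative OH• production, as
a tested invariant.

**Integration.** A Cash–Karp embedded Runge–Kutta 4(5) with per-species
mixed error control (`rtol = 1e-8`, `atol = 1e-16`) is the default; a
fixed-step classic RK4 (`dt ≤ 1 ms`) is kept as an independent oracle and
the two must agree to 10⁻³ relative on every species (tested). Tiny negative
round-off excursions are clamped to zero; materially negative states, step
underflow or non-finite states abort with explicit errors rather than
returning NaNs.

## The sensor model

The relaxation rate is linear in bulk paramagnetic concentrations:

$$1/T_1 = R_0 + r_{\mathrm{Cu}^{2+}}[\mathrm{Cu}^{2+}]
 + r_{\mathrm{OH}}[\mathrm{OH}^\bullet] + r_{\mathrm{O_2^-}}[\mathrm{O_2}^{\bullet-}].$$

The ~20 nm detection shell of the NV ensemble is absorbed into the
relaxivity coefficients rather than modelled geometrically. Diamagnetic
species (Cu⁺, H₂O₂, water) do not contribute. Triplet O₂ is paramagnetic
but excluded by default — whether it contributes in the real experiment is
not stated — and can be enabled via `sensor_params(r_o2 = ...)`.

Defaults: $R_0 = 1/300\,\mu s$ (a typical water-blank T1),
$r_{\mathrm{Cu}^{2+}} = 3\times10^7\ \mathrm{s^{-1}M^{-1}}$ so that 1 mM
copper depresses T1 to 30 µs (≈90% — comfortably beyond the reported >50%),
and radical relaxivities of $5\times10^9$, large per molar but negligible in
effect because radical steady states are sub-nanomolar, matching the
observation that the radicals themselves are barely visible to the sensor.
With the default photon yield (5000 counts per readout at τ→0, fractions
0.55/0.15/0.30 for offset/short/long, short component 8 µs) the
Cramér–Rao bound on a full-record T1 fit is ≈0.3 µs, which puts the 3σ
detection limit for copper in the sub-micromolar decade, consistent with the
claimed nanomolar-scale capability.

**Photon statistics.** Counts are Poisson per repetition and dark time
(optionally per readout time bin), seeded and byte-reproducible; `noise =
FALSE` returns the mean curve rounded half-to-even. The 10⁶–10⁷ counts-per-
second particle brightness used by quality control is carried as metadata
and deliberately decoupled from the per-readout yield.

## Analysis choices

* **Fit**: unweighted least squares (counts are large; inverse-variance
  weights are an option), `nls` "port" with non-negativity bounds, log-slope
  initialization, Nelder–Mead fallback/polish. $T_a \le T_b$ is enforced by
  relabelling — the model is symmetric in its components, so this is exact,
  not a constraint distortion. If $C_a$ collapses, $T_a$ is reported `NA`
  and the reported T1 remains $T_b$. Non-convergence flags the result
  instead of raising.
* **Moving window**: fixed length 2500, stride 100, so a 10,000-repetition
  record yields 76 windows and the last window ends exactly at repetition
  10,000. The published description ("1st–2500th", then "100–2600") is
  internally inconsistent about length 2500 vs 2501; this package fixes the
  length at 2500 and documents the choice.
* **Outliers**: Tukey IQR with factor 1.5 (the factor is unstated in the
  protocol) on linear-interpolation quartiles (R type 7). Zero-IQR series
  flag only values different from the median; fewer than four points flag
  nothing, with a warning.
* **Quality control**: brightness below 10⁶ cps → `excluded_intensity`;
  above 10⁷ cps → `excluded_aggregate` (the stated "obvious aggregates"
  exclusion operationalized as the intensity upper bound); fitted T1 above
  600 µs → `excluded_t1`.
* **Detection window**: the per-particle criterion is unstated in the
  protocol; this package maximizes the shot-noise contrast estimate
  $(S-R)/\sqrt{S+R}$ over all contiguous windows, breaking ties toward the
  shortest, earliest window. The search is exhaustive and deterministic.
* **T1 calibration**: levels span five decades (blank to millimolar), so the
  monotone (Hyman) spline interpolates in $\log_{10}(c + \epsilon)$ with
  $\epsilon$ = smallest nonzero level / 100 as a pseudo-log origin for the
  blank. Non-monotone mean sequences are flagged and refuse inversion —
  never silently reordered. Inversion refuses values outside the calibrated
  response range (no extrapolation) and, in sequence mode, refuses
  high-before-low measurement orders unless overridden, because copper
  adsorbs on the diamond surface and carries over into subsequent readings.
* **LOD**: 3σ rule (smallest concentration whose predicted response differs
  from the blank mean by three blank SDs) — the decision rule is this
  package's choice; the source claims only nanomolar capability.
* **Raman**: quantification uses baseline-corrected peak *height* at
  876 cm⁻¹ (the tracked quantity is the band intensity), after a multipoint
  piecewise-linear baseline through flanking anchors (default 820 and
  930 cm⁻¹). The correction is idempotent and exact on linear backgrounds;
  the default synthetic background is curved gently enough that peak heights
  are recovered within 1%.
* **Oxygen summary**: reports the pre-addition baseline, the endpoint
  reading, and two liberation conventions — endpoint − baseline (the
  generator convention, equal to the stoichiometric O₂ yield of R3 + R5 on a
  noiseless trace) and trailing-mean − baseline. The published "14 mg/L" is
  ambiguous between a final reading and a liberated amount; both numbers are
  returned and the generator convention is the default `liberated_mgL`.
* **Timeline**: all channels are linearly resampled onto a shared 1-minute
  grid over the 20-minute window; optical channels are normalized to their
  own maximum (100%), T1 to the water blank. The exact normalization of the
  published combined figure is unstated; the mode is recorded on the result.

## The synthetic world vs. real data

The generators emulate: second-order kinetics of the reaction network,
bi-exponential NV relaxation with Poisson shot noise, Beer–Lambert
absorbance, a Gaussian HTA emission band linear in concentration, a Gaussian
Raman band on a smooth polynomial background, and a noisy oxygen trace with
a flat pre-addition segment. Gaussian noise levels on the optical channels
are package choices (2×10⁻⁵ absorbance, 2 a.u. fluorescence, 3×10⁻³ a.u.
Raman, 0.05 mg/L oxygen) representative of routine benchtop instruments.

Two documented inconsistencies in the source are deliberately not resolved:
the Raman section states both a 3% band decrease at 100 mM H₂O₂ and
"roughly 0.3 mM consumed" (3% of 100 mM is 3 mM), so the Raman generator
exposes the band-decrease fraction directly (default 0.03) for the default
scenario and offers a trajectory-proportional mode for consistency checks;
and the Raman experiment's 100 mM peroxide differs from the 10 mM of the
other channels, so the Raman channel is a parallel scenario rather than a
literal render of the shared trajectory.

Not modelled: spatial diffusion or the 20 nm shell geometry, NV charge-state
photophysics, copper adsorption hysteresis on the diamond surface (only its
carry-over consequence is guarded against in calibration inversion),
instrument response functions, and resonance effects.

## Numerical conventions

Time is seconds internally (minutes in user-facing traces, µs for dark
times); concentrations are molar internally with µM/mM in reports; dissolved
oxygen uses 1 M = 32,000 mg/L (1 mg/L = 31.25 µM). Noiseless counts round
half-to-even. Sub-seeds for independent channels are derived
deterministically from the master seed and stay below 2³¹.
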