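# ndfenton

Nanodiamond T1 relaxometry is an optical, room-temperature form of nanoscale
magnetic resonance: nitrogen-vacancy (NV) centers in a fluorescent
nanodiamond relax from their optically polarized bright state faster when
paramagnetic species — Cu²⁺, hydroxyl radicals, superoxide — fluctuate
nearby. Tracking the longitudinal relaxation time T1 during a Cu(II)/H₂O₂
Fenton-like reaction therefore gives a real-time, nanomolar-scale readout of
the copper redox chemistry, which classic spectroscopies can only corroborate
in bulk.

`ndfenton` re-implements that measurement campaign as a tested, seeded
simulation-plus-analysis pipeline for anyone who wants to develop or validate
relaxometry analysis code without a magnetometer:

* a mass-action kinetic model of the copper-catalysed peroxide network
  (Cu²⁺ + H₂O₂ → Cu³⁺ + OH• + OH⁻; Cu²⁺ + H₂O₂ → Cu⁺ + O₂•⁻ + 2H⁺;
  Cu²⁺ + O₂•⁻ → Cu⁺ + O₂; OH• + H₂O₂ → HO₂•; 2 HO₂• → H₂O₂ + O₂;
  2 OH• → H₂O₂; Cu⁺ + H₂O₂ → Cu²⁺ + OH• + OH⁻; OH• + TH²⁻ → HTA),
  integrated with an adaptive Runge–Kutta 4(5) stepper in C++;
* synthetic generators for five mutually consistent measurement channels:
  NV photon-count relaxation records (Poisson shot noise, 10,000 repetitions,
  dark times 0.2 µs–10 ms), UV–Vis absorbance at 800 nm, terephthalate/HTA
  hydroxyl-radical dosimetry spectra, the 876 cm⁻¹ Raman band of H₂O₂, and a
  dissolved-oxygen sensor trace;
* the full analysis chain: constrained bi-exponential fitting of
  `PL(τ) = I_inf + C_a e^(−τ/T_a) + C_b e^(−τ/T_b)` (the long component is
  "the T1"), moving-window time-resolved T1 (2500-repetition windows, stride
  100), IQR outlier rejection, particle quality control (10⁶–10⁷ cps,
  T1 ≤ 600 µs), monotone T1↔[Cu²⁺] calibration with inversion and a 3σ limit
  of detection, Beer–Lambert quantification (ε = 12.6 M⁻¹cm⁻¹), multipoint
  Raman baseline correction, and a combined normalized reaction timeline.

Everything is tibble-first and pipe-friendly; results have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

```r
library(ndfenton)

# 1 mM Cu2+, 10 mM H2O2, 100 mM terephthalate trap, 20 min
traj <- simulate_kinetics()
traj[nrow(traj), c("time_s", "Cu2", "H2O2", "HTA", "O2")]
#> # A tibble: 1 × 5
#>   time_s      Cu2    H2O2         HTA       O2
#>    <dbl>    <dbl>   <dbl>       <dbl>    <dbl>
#> 1   1200 0.000800 0.00908 0.000000900 0.000437

# copper depletion seen by UV-Vis at 800 nm
uv <- generate_uvvis_trace(traj, noise_sd = 0)
beer_lambert_delta_c(uv, epsilon = 12.6, path = 1) * 1e3
#> [1] 0.2          # mM of Cu(II) consumed over 20 min

# T1 relaxometry: blank water vs 1 mM copper
s <- sensor_params()
rec <- generate_photon_counts(1e6 / (s$r0 + s$r_cu2 * 1e-3), seed = 1)
fit <- fit_biexponential(integrate_window(rec))
fit$reported_t1
#> [1] 30.00678     # us, vs the 300 us water baseline: ~90% depression

# time-resolved T1 within one acquisition
series <- moving_window_series(rec) |> iqr_filter()
nrow(series)
#> [1] 76           # 2500-repetition windows advanced by 100

# dissolved oxygen liberated by the catalytic peroxide decomposition
o2_summary(generate_o2_trace(traj, noise_sd = 0))$liberated_mgL
#> [1] 14           # mg/L above the 5 mg/L pre-addition baseline
```

The first number says the synthetic 800 nm kinetic trace, inverted through
Beer–Lambert, returns the 0.2 mM copper decrease the kinetic model was
parameterized to produce; the fitted 30 µs T1 against a 300 µs water blank is
the >50% T1 depression that makes 1 mM Cu²⁺ unmistakable to the NV sensor;
and the oxygen summary shows the 14 mg/L O₂ liberation accompanying the
reaction.

A full multi-channel run, ending in the combined normalized timeline:

```r
run <- run_full_pipeline(run_config(seed = 1, noiseless = TRUE))
autoplot(run$timeline)
```

`inst/scripts/run_pipeline.R` wraps the same call for shell use
(`--config`, `--seed`, `--out`, `--noiseless`, `--channel`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "ndfenton", load_package = "installed")'
```

## Acceptance script

`scripts/acceptance.R` regenerates every headline observable from scratch —
the kinetic simulation, all five synthetic channels, and their analyses
(copper decrease, hydroxyl-radical estimate, Raman band decay, T1 depression
across seeds, oxygen baseline and liberation) — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/nanodiamond-relaxometry.Rmd` documents the kinetic model and its
assumptions, the sensor and noise models, every tuned default, and what the
synthetic world does and does not establish about real measurements.
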