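# Shared fixtures, built in code.

# Mean Eq.-1 photoluminescence curve for the packaged sensor model.
biexp_mean <- function(tau_us, t1_us, sensor = sensor_params(),
                       n_pooled = 1) {
  n_pooled * sensor$photon_yield *
    (sensor$f_inf + sensor$f_short * exp(-tau_us / sensor$t_short_us) +
       sensor$f_long * exp(-tau_us / t1_us))
}

# Noiseless relaxation curve at a given long T1.
noiseless_curve <- function(t1_us, pulse = pulse_config(),
                            sensor = sensor_params(), n_pooled = 1e4) {
  new_relaxation_curve(pulse$tau_us,
                       biexp_mean(pulse$tau_us, t1_us, sensor, n_pooled),
                       n_pooled = n_pooled)
}

# A reduced pulse configuration for fast stochastic tests.
fast_pulse <- function(n_reps = 2000L) pulse_config(n_reps = n_reps)

# Full fit of a seeded Poisson record; returns the reported long T1 (us).
fitted_t1 <- function(t1_us, seed, pulse = pulse_config(),
                      sensor = sensor_params()) {
  rec <- generate_photon_counts(t1_us, pulse, sensor, seed = seed)
  fit_biexponential(integrate_window(rec))$reported_t1
}

# T1 ladder predicted by the packaged sensor model for a set of copper
# concentrations (M).
t1_for_cu <- function(conc_M, sensor = sensor_params()) {
  1e6 / (sensor$r0 + sensor$r_cu2 * conc_M)
}
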