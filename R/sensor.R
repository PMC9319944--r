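#' NV-sensor parameters of the nanodiamond relaxometer
#'
#' The relaxation model is linear in the bulk concentration of each
#' paramagnetic species: `1/T1 = R0 + r_cu2 [Cu2+] + r_oh [OH.] +
#' r_o2m [O2.-]`. The ~20 nm detection shell of the NV ensemble is absorbed
#' into the relaxivity coefficients rather than modelled geometrically.
#' Diamagnetic species (Cu+, H2O2, water) do not contribute; triplet O2 is
#' excluded by default but can be given a relaxivity via `r_o2`.
#'
#' The photon model describes the mean integrated fluorescence per readout as
#' a bi-exponential in the dark time tau: `I(tau) = yield * (f_inf +
#' f_short * exp(-tau/t_short) + f_long * exp(-tau/T1))`, the short component
#' standing for the fast-relaxing sub-ensemble of NV centers.
#'
#' @param r0 Baseline relaxation rate in ultrapure water (s^-1); the default
#'   corresponds to a 300 us blank T1.
#' @param r_cu2,r_oh,r_o2m,r_o2 Relaxivities (s^-1 M^-1) of Cu2+, OH.,
#'   superoxide and (optionally) molecular O2.
#' @param t_short_us Short-component relaxation time (us).
#' @param f_inf,f_short,f_long Amplitude fractions (must sum to 1).
#' @param photon_yield Mean integrated counts per readout at tau -> 0.
#' @param cps Nominal particle brightness in counts per second, used only as
#'   quality-control metadata.
#' @return A list of class `sensor_params`.
#' @export
sensor_params <- function(r0 = 1 / 300e-6,
                          r_cu2 = 3e7, r_oh = 5e9, r_o2m = 5e9, r_o2 = 0,
                          t_short_us = 8,
                          f_inf = 0.55, f_short = 0.15, f_long = 0.30,
                          photon_yield = 5000, cps = 5e6) {
  check_number(r0, "r0", positive = TRUE)
  for (nm in c("r_cu2", "r_oh", "r_o2m", "r_o2"))
    check_number(get(nm), nm, nonneg = TRUE)
  check_number(t_short_us, "t_short_us", positive = TRUE)
  check_number(photon_yield, "photon_yield", positive = TRUE)
  fr <- c(f_inf, f_short, f_long)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    abort("amplitude fractions must be >= 0 and sum to 1.")
  structure(list(r0 = r0, r_cu2 = r_cu2, r_oh = r_oh, r_o2m = r_o2m,
                 r_o2 = r_o2, t_short_us = t_short_us, f_inf = f_inf,
                 f_short = f_short, f_long = f_long,
                 photon_yield = photon_yield, cps = cps),
            class = "sensor_params")
}

#' Map a kinetic trajectory to the NV long-component T1
#'
#' Applies the linear relaxivity model of [sensor_params()] to the
#' paramagnetic species of a trajectory.
#'
#' @param traj A `kinetic_trajectory`.
#' @param sensor A [sensor_params()] object.
#' @return Tibble with `time_s`, `time_min`, `rate_per_s` and `t1_us`.
#' @export
trajectory_to_t1 <- function(traj, sensor = sensor_params()) {
  stopifnot(inherits(traj, "kinetic_trajectory"),
            inherits(sensor, "sensor_params"))
  rate <- sensor$r0 + sensor$r_cu2 * traj$Cu2 + sensor$r_oh * traj$OH +
    sensor$r_o2m * traj$O2m + sensor$r_o2 * traj$O2
  tibble::tibble(time_s = traj$time_s, time_min = traj$time_s / 60,
                 rate_per_s = rate, t1_us = 1e6 / rate)
}

#' Relaxometry pulse-sequence configuration
#'
#' Defaults follow the acquisition protocol: 5 us green polarization pulses,
#' dark times log-spaced between 0.2 us and 10 ms (count unstated in the
#' protocol; 21 points by default), 10,000 repetitions, and a 1 us detection
#' window at the head of the readout pulse.
#'
#' @param polarization_us Polarization pulse length (us).
#' @param tau_us Strictly increasing dark times (us) within [0.2, 10000].
#' @param n_reps Number of repetitions of the full dark-time sweep.
#' @param window_us Detection-window length (us).
#' @param acquisition_min Wall-clock duration of the full acquisition
#'   (minutes), used to timestamp moving-window estimates.
#' @return A list of class `pulse_config`.
#' @export
pulse_config <- function(polarization_us = 5,
                         tau_us = exp(seq(log(0.2), log(1e4), length.out = 21)),
                         n_reps = 10000,
                         window_us = 1,
                         acquisition_min = 10) {
  check_number(polarization_us, "polarization_us", positive = TRUE)
  check_increasing(tau_us, "tau_us")
  if (min(tau_us) < 0.2 - 1e-9 || max(tau_us) > 1e4 + 1e-6)
    abort("dark times must lie within [0.2 us, 10 ms].")
  check_number(n_reps, "n_reps", positive = TRUE)
  check_number(window_us, "window_us", positive = TRUE)
  check_number(acquisition_min, "acquisition_min", positive = TRUE)
  structure(list(polarization_us = polarization_us, tau_us = tau_us,
                 n_reps = as.integer(n_reps), window_us = window_us,
                 acquisition_min = acquisition_min),
            class = "pulse_config")
}
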