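#' Synthetic UV-Vis kinetic trace at 800 nm
#'
#' Renders the Beer-Lambert absorbance of the Cu2+ d-d band,
#' `A(t) = epsilon * path * [Cu2+](t)`, optionally with Gaussian noise.
#'
#' @param traj A `kinetic_trajectory`.
#' @param epsilon Molar absorptivity (M^-1 cm^-1); default the 800 nm value
#'   12.6.
#' @param path Cuvette path length in cm (default 1 cm, i.e. 10 mm).
#' @param noise_sd Gaussian noise standard deviation in absorbance units
#'   (0 = noiseless).
#' @param seed Seed for the noise draw.
#' @return A `scalar_trace` in absorbance units, one point per trajectory
#'   time.
#' @export
generate_uvvis_trace <- function(traj, epsilon = 12.6, path = 1,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  check_number(epsilon, "epsilon", positive = TRUE)
  check_number(path, "path", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  a <- epsilon * path * traj$Cu2
  if (noise_sd > 0)
    a <- a + with_seed(derive_seed(seed, 1L), rnorm(length(a), 0, noise_sd))
  new_scalar_trace(traj$time_s / 60, a, unit = "absorbance", addition_min = 0)
}

#' Synthetic HTA fluorescence emission spectra
#'
#' Gaussian emission band centred at 420 nm whose peak intensity is linear in
#' the hydroxyterephthalate (HTA) concentration, on a flat background;
#' emulates 330 nm excitation dosimeter spectra.
#'
#' @param hta_M Vector of HTA concentrations (molar), one spectrum each.
#' @param time_min Optional acquisition timestamps (minutes), recycled.
#' @param wavelength_nm Emission wavelength grid.
#' @param center_nm,width_nm Band centre and Gaussian sigma (nm).
#' @param intensity_per_M Peak intensity per molar HTA (default 1e9 a.u./M,
#'   i.e. 1000 a.u. per uM).
#' @param background Flat background level (a.u.).
#' @param noise_sd Gaussian noise sigma (a.u.).
#' @param seed Seed for the noise draws.
#' @return List of `spectrum` objects (channel `"fluorescence"`).
#' @export
generate_hta_spectra <- function(hta_M, time_min = NA_real_,
                                 wavelength_nm = seq(380, 480, by = 1),
                                 center_nm = 420, width_nm = 25,
                                 intensity_per_M = 1e9, background = 10,
                                 noise_sd = 0, seed = 1L) {
  if (any(!is.finite(hta_M)) || any(hta_M < 0))
    abort("HTA concentrations must be finite and >= 0.")
  check_number(intensity_per_M, "intensity_per_M", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  time_min <- rep_len(time_min, length(hta_M))
  shape <- exp(-(wavelength_nm - center_nm)^2 / (2 * width_nm^2))
  purrr::map2(seq_along(hta_M), hta_M, function(i, conc) {
    y <- background + intensity_per_M * conc * shape
    if (noise_sd > 0)
      y <- y + with_seed(derive_seed(seed, 10L + i),
                         rnorm(length(y), 0, noise_sd))
    new_spectrum(wavelength_nm, y, abscissa_unit = "nm",
                 time_min = time_min[i], channel = "fluorescence")
  })
}

#' Synthetic Raman spectra of the 876 cm-1 H2O2 band
#'
#' A Gaussian O-O stretch band at 876 cm-1 on a smooth cubic background.
#' Two amplitude conventions are supported:
#'
#' * trajectory mode (`traj` supplied): band amplitude proportional to
#'   `[H2O2](t)` via `amplitude_per_M`;
#' * dial mode (`traj = NULL`, the default scenario): the band starts at
#'   `amplitude_per_M * h2o2_0` and decays linearly so that it has dropped by
#'   the configured `band_decrease` fraction at `t_end_min`. This mirrors the
#'   reported experiment, which used a more concentrated 100 mM peroxide
#'   solution for Raman and quotes the band decrease itself (3%).
#'
#' @param times_min Acquisition times (minutes), one spectrum each.
#' @param traj Optional `kinetic_trajectory` driving the band amplitude.
#' @param h2o2_0 Dial-mode initial H2O2 concentration (molar, default
#'   100 mM).
#' @param band_decrease Dial-mode fractional band decrease at `t_end_min`
#'   (default 0.03).
#' @param t_end_min Dial-mode reaction end time (minutes).
#' @param wavenumber Raman shift grid (cm^-1).
#' @param center,width Band centre and Gaussian sigma (cm^-1).
#' @param amplitude_per_M Band amplitude per molar H2O2 (a.u./M).
#' @param background Length-4 polynomial coefficients (intercept, linear,
#'   quadratic, cubic in centred wavenumber) of the smooth background.
#' @param noise_sd Gaussian noise sigma (a.u.).
#' @param seed Seed for the noise draws.
#' @return List of `spectrum` objects (channel `"raman"`).
#' @export
generate_raman_spectra <- function(times_min, traj = NULL, h2o2_0 = 0.1,
                                   band_decrease = 0.03, t_end_min = 20,
                                   wavenumber = seq(700, 1050, by = 1),
                                   center = 876, width = 8,
                                   amplitude_per_M = 10,
                                   background = c(50, -0.02, 1e-6, 5e-9),
                                   noise_sd = 0, seed = 1L) {
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (!is.null(traj)) {
    stopifnot(inherits(traj, "kinetic_trajectory"))
    h2o2 <- concentration_at(traj, "H2O2", times_min * 60)
  } else {
    if (any(times_min < 0 | times_min > t_end_min))
      abort("`times_min` must lie within [0, t_end_min].")
    h2o2 <- h2o2_0 * (1 - band_decrease * times_min / t_end_min)
  }
  x <- wavenumber - center
  bg <- background[1] + background[2] * x + background[3] * x^2 +
    background[4] * x^3
  shape <- exp(-x^2 / (2 * width^2))
  purrr::map2(seq_along(times_min), h2o2, function(i, conc) {
    y <- bg + amplitude_per_M * conc * shape
    if (noise_sd > 0)
      y <- y + with_seed(derive_seed(seed, 20L + i),
                         rnorm(length(y), 0, noise_sd))
    new_spectrum(wavenumber, y, abscissa_unit = "cm-1",
                 time_min = times_min[i], channel = "raman")
  })
}

#' Synthetic dissolved-oxygen sensor trace
#'
#' `trace(t) = baseline + 32000 * [O2](t)` mg/L (32 g/mol molar mass; 1 M of
#' dissolved O2 corresponds to 32,000 mg/L, equivalently 1 mg/L = 31.25 uM).
#' A flat pre-addition segment at the baseline reading is prepended and the
#' peroxide-addition marker is set at t = 0.
#'
#' @param traj A `kinetic_trajectory` (O2 starts at zero at the marker).
#' @param baseline_mgL Pre-addition dissolved-oxygen reading (default
#'   5 mg/L).
#' @param pre_min Length of the pre-addition segment in minutes.
#' @param pre_points Number of pre-addition samples.
#' @param noise_sd Gaussian noise sigma (mg/L).
#' @param seed Seed for the noise draw.
#' @return A `scalar_trace` in mg/L with `addition_min = 0`.
#' @export
generate_o2_trace <- function(traj, baseline_mgL = 5, pre_min = 2,
                              pre_points = 24L, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  check_number(baseline_mgL, "baseline_mgL", nonneg = TRUE)
  check_number(pre_min, "pre_min", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  t_pre <- seq(-pre_min, 0, length.out = pre_points + 1L)
  t_pre <- t_pre[-length(t_pre)]
  tm <- c(t_pre, traj$time_s / 60)
  v <- c(rep(baseline_mgL, length(t_pre)), baseline_mgL + 32000 * traj$O2)
  if (noise_sd > 0)
    v <- v + with_seed(derive_seed(seed, 30L), rnorm(length(v), 0, noise_sd))
  new_scalar_trace(tm, v, unit = "mg/L", addition_min = 0)
}
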