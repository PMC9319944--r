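#' Assemble a full-pipeline run configuration
#'
#' Collects every tunable of the simulate -> analyze -> calibrate -> quantify
#' chain into one serializable list. Defaults describe the benchtop default
#' scenario: 1 mM CuSO4 + 10 mM H2O2 (+ 100 mM terephthalate trap), 20 min
#' reaction, the packaged sensor and pulse sequence, and per-channel noise
#' levels typical of the respective instruments.
#'
#' @param seed Integer master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param noiseless Disable all noise sources (overrides per-channel noise).
#' @param cu2_0,h2o2_0,th_0 Initial concentrations (molar).
#' @param t_end_s,dt_out_s Reaction duration and output grid spacing
#'   (seconds).
#' @param rates Named list/vector overriding [rate_constants()] entries.
#' @param sensor,pulse Named lists overriding [sensor_params()] /
#'   [pulse_config()] entries.
#' @param n_particles Number of simulated particles for the relaxometry
#'   channel; their baseline rates get a lognormal spread.
#' @param r0_spread_sdlog Lognormal sigma of the per-particle baseline
#'   relaxation rate.
#' @param uvvis_noise_sd,hta_noise_sd,raman_noise_sd,o2_noise_sd Channel
#'   noise levels (absorbance / a.u. / a.u. / mg/L).
#' @param hta_calib_uM HTA calibration ladder (uM).
#' @param raman_times_min,raman_band_decrease,raman_h2o2_0 Raman channel
#'   settings (dial mode; see [generate_raman_spectra()]).
#' @param o2_baseline_mgL Pre-addition dissolved-oxygen reading.
#' @param normalization `"max"` or `"baseline"` for the combined timeline.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L, noiseless = FALSE,
                       cu2_0 = 1e-3, h2o2_0 = 1e-2, th_0 = 0.1,
                       t_end_s = 1200, dt_out_s = 5,
                       rates = list(), sensor = list(), pulse = list(),
                       n_particles = 1L, r0_spread_sdlog = 0.1,
                       uvvis_noise_sd = 2e-5, hta_noise_sd = 2,
                       raman_noise_sd = 0.003, o2_noise_sd = 0.05,
                       hta_calib_uM = c(0.2, 0.4, 0.6, 0.8, 1.0),
                       raman_times_min = seq(0, 20, by = 2),
                       raman_band_decrease = 0.03, raman_h2o2_0 = 0.1,
                       o2_baseline_mgL = 5,
                       normalization = c("max", "baseline")) {
  normalization <- match.arg(normalization)
  cfg <- list(
    seed = as.integer(seed), noiseless = isTRUE(noiseless),
    kinetics = list(cu2_0 = cu2_0, h2o2_0 = h2o2_0, th_0 = th_0,
                    t_end_s = t_end_s, dt_out_s = dt_out_s,
                    rates = as.list(do.call(rate_constants, as.list(rates)))),
    sensor = unclass(do.call(sensor_params, sensor)),
    pulse = {
      p <- do.call(pulse_config, pulse)
      list(polarization_us = p$polarization_us, tau_us = p$tau_us,
           n_reps = p$n_reps, window_us = p$window_us,
           acquisition_min = p$acquisition_min)
    },
    relaxometry = list(n_particles = as.integer(n_particles),
                       r0_spread_sdlog = r0_spread_sdlog),
    uvvis = list(epsilon = 12.6, path_cm = 1, noise_sd = uvvis_noise_sd),
    hta = list(calib_uM = hta_calib_uM, noise_sd = hta_noise_sd),
    raman = list(times_min = raman_times_min,
                 band_decrease = raman_band_decrease, h2o2_0 = raman_h2o2_0,
                 anchors = c(820, 930), noise_sd = raman_noise_sd),
    o2 = list(baseline_mgL = o2_baseline_mgL, pre_min = 2,
              noise_sd = o2_noise_sd),
    normalization = normalization
  )
  names(cfg$kinetics$rates) <- names(unclass(rate_constants()))
  structure(cfg, class = "run_config")
}

#' Normalize a series for the combined timeline
#'
#' @param values Numeric series.
#' @param mode `"max"` (percent of the series maximum) or `"baseline"`
#'   (percent of the baseline mean).
#' @param baseline Baseline values (required for `mode = "baseline"`).
#' @return Normalized series in percent, with the mode and reference stored
#'   as attributes.
#' @export
normalize_series <- function(values, mode = c("max", "baseline"),
                             baseline = NULL) {
  mode <- match.arg(mode)
  ref <- switch(mode,
                max = max(values),
                baseline = {
                  if (is.null(baseline)) abort("`baseline` required for baseline mode.")
                  mean(baseline)
                })
  if (!is.finite(ref) || ref == 0) abort("normalization reference is zero.")
  structure(100 * values / ref, mode = mode, reference = ref)
}

#' Run the full multi-channel pipeline
#'
#' One seeded kinetic simulation of the default scenario feeds all five
#' measurement channels; each channel is then analyzed by its own module and
#' the results are resampled onto a shared 1-minute grid as a combined,
#' normalized reaction timeline (T1, Cu2+ from UV-Vis, H2O2 from Raman,
#' hydroxyl radical from HTA dosimetry, dissolved O2).
#'
#' @param config A [run_config()].
#' @return A `fenton_run` list: `timeline` (a `timeline_table` tibble),
#'   `trajectory`, `channels` (per-channel artifacts), `calibrations`,
#'   `log` (character vector of every decision, seed and QC exclusion) and
#'   the echoed `config`.
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", label,
                    conditionMessage(e))))
  }
  noiseless <- config$noiseless
  seed <- config$seed
  note("run seed %d; noiseless = %s", seed, noiseless)

  kin <- config$kinetics
  traj <- stage("simulate", simulate_kinetics(
    initial = initial_state(cu2 = kin$cu2_0, h2o2 = kin$h2o2_0, th = kin$th_0),
    rates = do.call(rate_constants, kin$rates),
    t_grid = seq(0, kin$t_end_s, by = kin$dt_out_s)))
  note("kinetics: %d time points over %g s", nrow(traj), kin$t_end_s)

  sensor <- do.call(sensor_params, config$sensor)
  pulse <- do.call(pulse_config,
                   config$pulse[setdiff(names(config$pulse), character())])
  # stretch the acquisition clock over the full reaction window so the
  # moving-window series time-resolves the whole 20 min reaction
  pulse$acquisition_min <- kin$t_end_s / 60

  relax <- stage("relaxometry", {
    t1_true <- trajectory_to_t1(traj, sensor)
    n_part <- config$relaxometry$n_particles
    r0_mult <- if (n_part > 1L) {
      with_seed(derive_seed(seed, 100L),
                exp(rnorm(n_part, 0, config$relaxometry$r0_spread_sdlog)))
    } else 1
    series_list <- purrr::map(seq_len(n_part), function(p) {
      s_p <- sensor; s_p$r0 <- sensor$r0 * r0_mult[p]
      rep_times <- seq(0, kin$t_end_s,
                       length.out = pulse$n_reps)
      t1_rep <- 1e6 / (s_p$r0 +
                         approx(t1_true$time_s, t1_true$rate_per_s - sensor$r0,
                                xout = rep_times)$y)
      rec <- generate_photon_counts(t1_rep, pulse, s_p,
                                    seed = derive_seed(seed, 200L + p),
                                    noise = !noiseless)
      ser <- iqr_filter(moving_window_series(rec))
      n_out <- sum(ser$outlier)
      if (n_out > 0) note("particle %d: %d moving-window outliers flagged", p, n_out)
      blank_rec <- generate_photon_counts(1e6 / s_p$r0, pulse, s_p,
                                          seed = derive_seed(seed, 300L + p),
                                          noise = !noiseless)
      blank_t1 <- fit_biexponential(integrate_window(blank_rec))$reported_t1
      ser$particle <- p
      ser$blank_t1_us <- blank_t1
      ser
    })
    dplyr::bind_rows(series_list)
  })
  note("relaxometry: %d particles, %d window fits",
       config$relaxometry$n_particles, nrow(relax))

  uv <- config$uvvis
  uvvis <- stage("uvvis", generate_uvvis_trace(
    traj, epsilon = uv$epsilon, path = uv$path_cm,
    noise_sd = if (noiseless) 0 else uv$noise_sd,
    seed = derive_seed(seed, 400L)))

  hta_cfg <- config$hta
  hta <- stage("hta", {
    # a blank level is prepended so the reaction series (which starts at
    # zero trapped HTA) stays inside the calibrated range
    calib_conc <- c(0, hta_cfg$calib_uM * 1e-6)
    calib_spectra <- generate_hta_spectra(
      calib_conc, noise_sd = if (noiseless) 0 else hta_cfg$noise_sd,
      seed = derive_seed(seed, 500L))
    calib <- fit_fluorescence_calibration(tibble::tibble(
      concentration_M = calib_conc,
      intensity = purrr::map_dbl(calib_spectra, ~ peak_at(.x, 420))))
    times <- seq(0, kin$t_end_s / 60, by = 1)
    rx_spectra <- generate_hta_spectra(
      concentration_at(traj, "HTA", times * 60), time_min = times,
      noise_sd = if (noiseless) 0 else hta_cfg$noise_sd,
      seed = derive_seed(seed, 501L))
    intens <- purrr::map_dbl(rx_spectra, ~ peak_at(.x, 420))
    # noise can push an intensity marginally outside the calibrated range;
    # clamp to the range limits rather than refuse the whole series
    oh_uM <- quantify_oh(calib, pmin(pmax(intens, calib$intensity_range[1]),
                                     calib$intensity_range[2]))
    list(calibration = calib, spectra = rx_spectra,
         series = tibble::tibble(time_min = times, oh_uM = oh_uM))
  })
  note("hta: calibration slope %.4g a.u./M, R^2 %.6f",
       hta$calibration$slope, hta$calibration$r_squared)

  rm_cfg <- config$raman
  raman <- stage("raman", {
    spectra <- generate_raman_spectra(
      rm_cfg$times_min, h2o2_0 = rm_cfg$h2o2_0,
      band_decrease = rm_cfg$band_decrease,
      t_end_min = kin$t_end_s / 60,
      noise_sd = if (noiseless) 0 else rm_cfg$noise_sd,
      seed = derive_seed(seed, 600L))
    peaks <- purrr::map_dbl(spectra, function(sp)
      peak_intensity(multipoint_baseline(sp, rm_cfg$anchors)))
    list(spectra = spectra,
         series = tibble::tibble(time_min = rm_cfg$times_min, peak = peaks),
         decrease_pct = fractional_decrease(peaks[1], peaks[length(peaks)]))
  })
  note("raman: 876 cm-1 band decrease %.3f%%", raman$decrease_pct)

  o2_cfg <- config$o2
  o2 <- stage("o2", {
    trace <- generate_o2_trace(traj, baseline_mgL = o2_cfg$baseline_mgL,
                               pre_min = o2_cfg$pre_min,
                               noise_sd = if (noiseless) 0 else o2_cfg$noise_sd,
                               seed = derive_seed(seed, 700L))
    list(trace = trace, summary = o2_summary(trace))
  })
  note("o2: baseline %.3f mg/L, liberated %.3f mg/L",
       o2$summary$baseline_mgL, o2$summary$liberated_mgL)

  timeline <- stage("timeline", {
    grid_min <- seq(0, kin$t_end_s / 60, by = 1)
    res <- function(t, v) approx(t, v, xout = grid_min, rule = 2)$y
    # an identically-zero channel (e.g. a copper-free run) has no
    # normalization reference; report it as a flat zero series
    norm_or_flat <- function(v, mode) {
      if (max(abs(v)) == 0) {
        note("timeline: identically-zero channel kept as flat 0%%")
        rep(0, length(v))
      } else as.numeric(normalize_series(v, mode))
    }
    kept <- dplyr::filter(relax, !.data$outlier)
    t1_avg <- dplyr::summarise(dplyr::group_by(kept, .data$time_min),
                               t1_us = mean(.data$t1_us), .groups = "drop")
    blank_mean <- mean(unique(relax$blank_t1_us))
    t1_pct <- normalize_t1(res(t1_avg$time_min, t1_avg$t1_us), blank_mean)
    post <- dplyr::filter(o2$trace, .data$time_min >= 0)
    tibble::tibble(
      time_min = grid_min,
      t1_pct_of_blank = as.numeric(t1_pct),
      cu_uvvis_pct = norm_or_flat(
        res(uvvis$time_min, uvvis$value), config$normalization),
      h2o2_raman_pct = norm_or_flat(
        res(raman$series$time_min, raman$series$peak), config$normalization),
      oh_hta_pct = norm_or_flat(
        res(hta$series$time_min, pmax(hta$series$oh_uM, 0)),
        config$normalization),
      o2_pct = norm_or_flat(
        res(post$time_min, post$value), config$normalization)
    )
  })
  timeline <- structure(timeline,
                        channels = c(t1_pct_of_blank = "relaxometry",
                                     cu_uvvis_pct = "uvvis",
                                     h2o2_raman_pct = "raman",
                                     oh_hta_pct = "hta", o2_pct = "o2"),
                        normalization = config$normalization,
                        class = c("timeline_table", class(timeline)))
  structure(list(timeline = timeline, trajectory = traj,
                 channels = list(relaxometry = relax, uvvis = uvvis,
                                 hta = hta, raman = raman, o2 = o2),
                 calibrations = list(hta = hta$calibration),
                 log = log, config = config),
            class = "fenton_run")
}

# intensity of a spectrum at one abscissa value (linear interpolation)
peak_at <- function(spectrum, x) {
  approx(spectrum$abscissa, spectrum$intensity, xout = x)$y
}

#' @export
print.fenton_run <- function(x, ...) {
  cat("Fenton-like reaction pipeline run\n")
  cat(sprintf("  seed %d, noiseless = %s\n", x$config$seed, x$config$noiseless))
  cat(sprintf("  timeline: %d time points, channels: %s\n",
              nrow(x$timeline),
              paste(names(attr(x$timeline, "channels")), collapse = ", ")))
  invisible(x)
}
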