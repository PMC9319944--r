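#' Generate synthetic NV photon-count records
#'
#' Draws per-repetition, per-dark-time integrated fluorescence counts whose
#' expectation follows the bi-exponential relaxation law
#' `I(tau) = I_inf + C_a exp(-tau/T_a) + C_b exp(-tau/T_b)` with the long
#' component `T_b` set by `t1_long_us`. Shot noise is Poisson; with
#' `noise = FALSE` the mean curve is returned, rounded half-to-even to
#' integer counts.
#'
#' @param t1_long_us Long-component T1 in us; either a single value or one
#'   value per repetition (used to emulate a reaction evolving during the
#'   acquisition).
#' @param pulse A [pulse_config()].
#' @param sensor A [sensor_params()].
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical records.
#' @param noise Draw Poisson shot noise (default) or return the rounded mean
#'   curve.
#' @param time_resolved If `TRUE`, counts are additionally resolved into
#'   `n_bins` equal time bins across the detection window (a `bin` column is
#'   added), for use with [integrate_window()].
#' @param n_bins Number of readout time bins when `time_resolved = TRUE`.
#' @return A `photon_count_record`: tibble with columns `repetition`,
#'   `tau_us`, (`bin`,) `counts`; attributes `pulse`, `sensor`, `seed`,
#'   `t1_true_us`, `cps`.
#' @export
generate_photon_counts <- function(t1_long_us, pulse = pulse_config(),
                                   sensor = sensor_params(), seed = 1L,
                                   noise = TRUE, time_resolved = FALSE,
                                   n_bins = 10L) {
  stopifnot(inherits(pulse, "pulse_config"), inherits(sensor, "sensor_params"))
  if (any(!is.finite(t1_long_us)) || any(t1_long_us <= 0))
    abort("`t1_long_us` must be positive and finite.")
  if (sensor$photon_yield <= 0) abort("photon yield must be > 0.")
  n <- pulse$n_reps
  if (!length(t1_long_us) %in% c(1L, n))
    abort("`t1_long_us` must have length 1 or `n_reps`.")
  t1 <- rep_len(t1_long_us, n)
  tau <- pulse$tau_us

  # mean counts per readout: repetitions x dark times
  mu <- sensor$photon_yield *
    (sensor$f_inf +
       sensor$f_short * exp(-outer(rep(1, n), tau) / sensor$t_short_us) +
       sensor$f_long * exp(-outer(1 / t1, tau)))

  grid <- tidyr::expand_grid(repetition = seq_len(n), tau_us = tau)
  if (time_resolved) {
    n_bins <- as.integer(n_bins)
    if (n_bins < 1L) abort("`n_bins` must be >= 1.")
    grid <- tidyr::expand_grid(repetition = seq_len(n), tau_us = tau,
                               bin = seq_len(n_bins))
    # flatten row-major to match expand_grid order, then split across bins
    mu_flat <- rep(as.vector(t(mu)), each = n_bins) / n_bins
    counts <- if (noise) {
      with_seed(derive_seed(seed), rpois(length(mu_flat), mu_flat))
    } else round_counts(mu_flat)
  } else {
    mu_flat <- as.vector(t(mu))
    counts <- if (noise) {
      with_seed(derive_seed(seed), rpois(length(mu_flat), mu_flat))
    } else round_counts(mu_flat)
  }
  out <- tibble::add_column(grid, counts = as.integer(counts))
  structure(out, pulse = pulse, sensor = sensor, seed = as.integer(seed),
            t1_true_us = t1_long_us, cps = sensor$cps,
            class = c("photon_count_record", class(out)))
}

#' Choose the detection window that maximizes spin-state contrast
#'
#' Scans every contiguous window of readout time bins and returns the one
#' maximizing the shot-noise-limited contrast estimate
#' `(S - R) / sqrt(S + R)`, where `S` sums the polarized (bright,
#' short-dark-time) trace and `R` the relaxed reference trace over the window.
#' Ties are broken toward the shortest window, then the earliest start; the
#' search is exhaustive, hence deterministic.
#'
#' @param trace Tibble with columns `t_us` (bin start time, strictly
#'   increasing, equal widths), `signal` and `reference` (non-negative
#'   pooled counts per bin).
#' @return List with `start` and `length` (bin indices), `start_us`,
#'   `length_us` and the achieved `contrast`.
#' @export
determine_detection_window <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("t_us", "signal", "reference") %in% names(trace)))
  check_increasing(trace$t_us, "t_us")
  s <- as.numeric(trace$signal); r <- as.numeric(trace$reference)
  if (any(s < 0) || any(r < 0)) abort("counts must be non-negative.")
  if (all(s == 0) && all(r == 0)) abort("no contrast: trace is all zero.")
  nb <- length(s)
  cs <- c(0, cumsum(s)); cr <- c(0, cumsum(r))
  best <- list(contrast = -Inf, start = NA_integer_, length = NA_integer_)
  for (len in seq_len(nb)) {
    for (st in seq_len(nb - len + 1L)) {
      S <- cs[st + len] - cs[st]; R <- cr[st + len] - cr[st]
      contrast <- if (S + R > 0) (S - R) / sqrt(S + R) else 0
      if (contrast > best$contrast + 1e-12) {
        best <- list(contrast = contrast, start = st, length = len)
      }
    }
  }
  if (!is.finite(best$contrast) || best$contrast <= 0)
    abort("no contrast: signal does not exceed reference in any window.")
  dt <- diff(trace$t_us)[1]
  list(start = best$start, length = best$length,
       start_us = trace$t_us[best$start], length_us = best$length * dt,
       contrast = best$contrast)
}

#' Integrate a photon-count record into a relaxation curve
#'
#' Pools counts over a repetition span (and, for time-resolved records, over
#' the detection-window bins) to give one photoluminescence value per dark
#' time.
#'
#' @param record A `photon_count_record`.
#' @param window Integer vector of readout bin indices to integrate
#'   (time-resolved records only; `NULL` for pre-integrated records).
#' @param span Repetition span `c(first, last)`; defaults to all repetitions.
#' @return A `relaxation_curve`: tibble with `tau_us` and `pl` (summed
#'   counts), with the pooled repetition count as attribute `n_pooled`.
#' @export
integrate_window <- function(record, window = NULL, span = NULL) {
  stopifnot(inherits(record, "photon_count_record") || is.data.frame(record))
  pulse <- attr(record, "pulse")
  n <- if (!is.null(pulse)) pulse$n_reps else max(record$repetition)
  if (is.null(span)) span <- c(1L, n)
  if (length(span) != 2L || span[1] > span[2] || span[1] < 1L)
    abort("`span` must be c(first, last) with first <= last.")
  dat <- dplyr::filter(record, .data$repetition >= span[1],
                       .data$repetition <= span[2])
  if (nrow(dat) == 0L) abort("empty repetition span.")
  if ("bin" %in% names(record)) {
    if (is.null(window)) abort("time-resolved record: supply `window` bin indices.")
    if (any(!window %in% unique(record$bin)))
      abort("`window` must index existing readout bins.")
    dat <- dplyr::filter(dat, .data$bin %in% window)
  } else if (!is.null(window)) {
    abort("`window` given but the record is not time-resolved.")
  }
  out <- dplyr::summarise(dplyr::group_by(dat, .data$tau_us),
                          pl = sum(as.numeric(.data$counts)), .groups = "drop")
  out <- dplyr::arrange(out, .data$tau_us)
  new_relaxation_curve(out$tau_us, out$pl,
                       n_pooled = span[2] - span[1] + 1L)
}

#' Construct a relaxation curve
#'
#' @param tau_us Strictly increasing dark times (us).
#' @param pl Non-negative integrated photoluminescence per dark time.
#' @param n_pooled Number of repetitions pooled into `pl`.
#' @return Tibble of class `relaxation_curve`.
#' @export
new_relaxation_curve <- function(tau_us, pl, n_pooled = 1L) {
  check_increasing(tau_us, "tau_us")
  if (length(pl) != length(tau_us) || any(!is.finite(pl)) || any(pl < 0))
    abort("`pl` must be non-negative and match `tau_us` in length.")
  out <- tibble::tibble(tau_us = as.numeric(tau_us), pl = as.numeric(pl))
  structure(out, n_pooled = as.integer(n_pooled),
            class = c("relaxation_curve", class(out)))
}
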