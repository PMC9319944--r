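#' Extract a kinetic trace at a fixed wavelength
#'
#' Pulls the intensity at one abscissa value out of a time series of spectra
#' (linear interpolation between abscissa nodes; at a node the stored
#' intensity is returned exactly).
#'
#' @param spectra List of `spectrum` objects with timestamps.
#' @param wavelength Abscissa value (same unit as the spectra); must lie
#'   within every spectrum's range.
#' @return A `scalar_trace` (absorbance units for UV-Vis input).
#' @export
kinetic_trace <- function(spectra, wavelength) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  vals <- purrr::map_dbl(spectra, function(sp) {
    stopifnot(inherits(sp, "spectrum"))
    if (wavelength < min(sp$abscissa) || wavelength > max(sp$abscissa))
      abort(sprintf("wavelength %g outside spectral range [%g, %g].",
                    wavelength, min(sp$abscissa), max(sp$abscissa)))
    approx(sp$abscissa, sp$intensity, xout = wavelength)$y
  })
  tm <- purrr::map_dbl(spectra, ~ attr(.x, "time_min"))
  if (any(!is.finite(tm))) abort("every spectrum needs a finite timestamp.")
  ord <- order(tm)
  unit <- if (attr(spectra[[1]], "channel") == "uvvis") "absorbance" else "a.u."
  new_scalar_trace(tm[ord], vals[ord], unit = unit)
}

#' Concentration change from a Beer-Lambert absorbance trace
#'
#' `delta_c = (A_first - A_last) / (epsilon * path)`; positive values mean
#' depletion of the absorbing species.
#'
#' @param trace A `scalar_trace` in absorbance units.
#' @param epsilon Molar absorptivity (M^-1 cm^-1).
#' @param path Path length (cm).
#' @return Concentration change in molar (positive = depletion).
#' @export
beer_lambert_delta_c <- function(trace, epsilon = 12.6, path = 1) {
  stopifnot(is.data.frame(trace), all(c("time_min", "value") %in% names(trace)))
  check_number(epsilon, "epsilon", positive = TRUE)
  check_number(path, "path", positive = TRUE)
  if (any(!is.finite(trace$value))) abort("absorbance values must be finite.")
  (trace$value[1] - trace$value[nrow(trace)]) / (epsilon * path)
}

#' Multipoint baseline correction
#'
#' Subtracts the piecewise-linear baseline passing through the spectrum's
#' (interpolated) intensities at the anchor abscissae; beyond the outermost
#' anchors the baseline continues at the end-anchor value. Corrected
#' intensity at each anchor is exactly zero, and the operation is idempotent.
#'
#' @param spectrum A `spectrum`.
#' @param anchors At least two anchor abscissae, all inside the spectral
#'   range.
#' @return The baseline-corrected `spectrum`.
#' @export
multipoint_baseline <- function(spectrum, anchors) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (length(anchors) < 2L) abort("at least two baseline anchors are required.")
  rng <- range(spectrum$abscissa)
  if (any(anchors < rng[1]) || any(anchors > rng[2]))
    abort("baseline anchors must lie inside the spectral range.")
  anchors <- sort(anchors)
  a_y <- approx(spectrum$abscissa, spectrum$intensity, xout = anchors)$y
  base <- approx(anchors, a_y, xout = spectrum$abscissa, rule = 2)$y
  out <- spectrum
  out$intensity <- spectrum$intensity - base
  out
}

#' Peak intensity within a band window
#'
#' Maximum of the (baseline-corrected) spectrum within
#' `[center - half_window, center + half_window]`.
#'
#' @param spectrum A `spectrum` (apply [multipoint_baseline()] first).
#' @param center Band centre (default the 876 cm-1 H2O2 O-O stretch).
#' @param half_window Half-width of the search window.
#' @return Peak intensity (a.u.).
#' @export
peak_intensity <- function(spectrum, center = 876, half_window = 30) {
  stopifnot(inherits(spectrum, "spectrum"))
  sel <- spectrum$abscissa >= center - half_window &
    spectrum$abscissa <= center + half_window
  if (!any(sel)) abort("peak window lies outside the spectral range.")
  max(spectrum$intensity[sel])
}

#' Percent decrease between two intensities
#'
#' @param i0 Intensity at the initial time (> 0).
#' @param i_n Intensity at the final time.
#' @return `100 * (i0 - i_n) / i0` (percent).
#' @export
fractional_decrease <- function(i0, i_n) {
  if (!is.finite(i0) || i0 <= 0) abort("initial intensity must be > 0.")
  100 * (i0 - i_n) / i0
}

#' Summarize a dissolved-oxygen trace
#'
#' Reports the pre-addition baseline (mean of all points before the
#' peroxide-addition marker), the endpoint reading, the mean of the trailing
#' fraction of the trace, and the liberated oxygen. Two liberation
#' conventions are computed: the generator convention `final reading -
#' baseline` (the stoichiometric O2 yield when the trace is noiseless) is
#' reported as `liberated_mgL`, and `trailing mean - baseline` as
#' `delta_mgL`; both are returned so neither reading of the ambiguous
#' published figure is asserted alone.
#'
#' @param trace A `scalar_trace` in mg/L.
#' @param addition_min Event marker (minutes); defaults to the marker stored
#'   on the trace.
#' @param trailing_fraction Fraction of the trace length used for the
#'   trailing mean (default 0.05).
#' @return A list: `baseline_mgL`, `final_mgL` (trailing mean),
#'   `endpoint_mgL`, `liberated_mgL`, `delta_mgL`.
#' @export
o2_summary <- function(trace, addition_min = NULL, trailing_fraction = 0.05) {
  stopifnot(is.data.frame(trace), all(c("time_min", "value") %in% names(trace)))
  if (is.null(addition_min)) addition_min <- attr(trace, "addition_min")
  if (is.null(addition_min) || !is.finite(addition_min))
    abort("an H2O2-addition marker is required (addition_min).")
  pre <- trace$value[trace$time_min < addition_min]
  if (!length(pre)) abort("no points before the addition marker.")
  post <- trace$value[trace$time_min >= addition_min]
  if (!length(post)) abort("no points after the addition marker.")
  n_tail <- max(1L, ceiling(trailing_fraction * nrow(trace)))
  baseline <- mean(pre)
  endpoint <- trace$value[nrow(trace)]
  final <- mean(tail(trace$value, n_tail))
  list(baseline_mgL = baseline,
       final_mgL = final,
       endpoint_mgL = endpoint,
       liberated_mgL = endpoint - baseline,
       delta_mgL = final - baseline)
}
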