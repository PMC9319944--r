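#' Construct a spectrum object
#'
#' Two-column spectral data with mandatory unit metadata: wavelength (nm) for
#' UV-Vis and fluorescence, wavenumber (cm^-1) for Raman.
#'
#' @param abscissa Strictly increasing wavelength/wavenumber vector.
#' @param intensity Intensity (a.u.) or absorbance.
#' @param abscissa_unit `"nm"` or `"cm-1"`.
#' @param intensity_unit e.g. `"a.u."` or `"absorbance"`.
#' @param time_min Acquisition timestamp in minutes (may be `NA`).
#' @param channel One of `"uvvis"`, `"fluorescence"`, `"raman"`.
#' @return Tibble of class `spectrum` with attributes carrying the metadata.
#' @export
new_spectrum <- function(abscissa, intensity,
                         abscissa_unit = c("nm", "cm-1"),
                         intensity_unit = "a.u.",
                         time_min = NA_real_,
                         channel = c("uvvis", "fluorescence", "raman")) {
  abscissa_unit <- match.arg(abscissa_unit)
  channel <- match.arg(channel)
  check_increasing(abscissa, "abscissa")
  if (length(intensity) != length(abscissa) || any(!is.finite(intensity)))
    abort("`intensity` must be finite and match `abscissa` in length.")
  out <- tibble::tibble(abscissa = as.numeric(abscissa),
                        intensity = as.numeric(intensity))
  structure(out, abscissa_unit = abscissa_unit,
            intensity_unit = intensity_unit, time_min = as.numeric(time_min),
            channel = channel, class = c("spectrum", class(out)))
}

#' Construct a time-stamped scalar trace
#'
#' @param time_min Strictly increasing time in minutes.
#' @param value Measured value.
#' @param unit `"absorbance"` or `"mg/L"`.
#' @param addition_min Event marker: time (minutes) at which H2O2 was added,
#'   or `NA`.
#' @return Tibble of class `scalar_trace`.
#' @export
new_scalar_trace <- function(time_min, value,
                             unit = c("absorbance", "mg/L", "a.u."),
                             addition_min = NA_real_) {
  unit <- match.arg(unit)
  check_increasing(time_min, "time_min", allow_single = TRUE)
  if (length(value) != length(time_min) || any(!is.finite(value)))
    abort("`value` must be finite and match `time_min` in length.")
  out <- tibble::tibble(time_min = as.numeric(time_min),
                        value = as.numeric(value))
  structure(out, unit = unit, addition_min = as.numeric(addition_min),
            class = c("scalar_trace", class(out)))
}
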