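# File formats. All CSV writers emit a commented header ("# key: value"
# lines) stating units and configuration; readers validate it and report
# parse failures with the offending line number.

write_header <- function(path, meta, df) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_commented_csv <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1))
    abort(sprintf("malformed header in '%s': comment line %d appears after data.",
                  path, hdr_idx[which(diff(hdr_idx) != 1)[1] + 1L]))
  meta <- list()
  for (i in hdr_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      abort(sprintf("malformed header in '%s' at line %d: '%s'", path, i, lines[i]))
    meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  if (!length(body)) abort(sprintf("no data rows in '%s'.", path))
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"), check.names = FALSE),
    error = function(e)
      abort(sprintf("parse error in '%s' after line %d: %s", path,
                    length(hdr_idx), conditionMessage(e))))
  list(meta = meta, data = tibble::as_tibble(df))
}

#' Write / read photon-count records as CSV
#'
#' Columns `repetition`, `tau_us`, `counts` (plus `bin` for time-resolved
#' records); the commented header carries the pulse configuration and seed so
#' a round trip is lossless.
#'
#' @param record A `photon_count_record`.
#' @param path Output / input CSV path.
#' @return `write_photon_counts()` returns `path` invisibly;
#'   `read_photon_counts()` returns the reconstructed record.
#' @export
write_photon_counts <- function(record, path) {
  stopifnot(inherits(record, "photon_count_record"))
  pulse <- attr(record, "pulse")
  meta <- list(format = "ndfenton photon counts v1",
               units = "tau_us in microseconds; counts dimensionless",
               tau_us = format(pulse$tau_us, digits = 17),
               n_reps = pulse$n_reps,
               polarization_us = pulse$polarization_us,
               window_us = pulse$window_us,
               acquisition_min = pulse$acquisition_min,
               seed = attr(record, "seed"),
               cps = attr(record, "cps"))
  write_header(path, meta, as.data.frame(record))
  invisible(path)
}

#' @rdname write_photon_counts
#' @export
read_photon_counts <- function(path) {
  parsed <- read_commented_csv(path)
  need <- c("repetition", "tau_us", "counts")
  if (!all(need %in% names(parsed$data)))
    abort(sprintf("'%s': expected columns %s.", path, toString(need)))
  meta <- parsed$meta
  pulse <- pulse_config(
    polarization_us = as.numeric(meta$polarization_us %||% 5),
    tau_us = as.numeric(strsplit(meta$tau_us, "\\s+")[[1]]),
    n_reps = as.integer(meta$n_reps %||% max(parsed$data$repetition)),
    window_us = as.numeric(meta$window_us %||% 1),
    acquisition_min = as.numeric(meta$acquisition_min %||% 10))
  out <- parsed$data
  if (any(out$counts < 0)) abort(sprintf("'%s': negative counts.", path))
  structure(out, pulse = pulse,
            seed = as.integer(meta$seed %||% NA_integer_),
            cps = as.numeric(meta$cps %||% NA_real_),
            class = c("photon_count_record", class(out)))
}

#' Write / read two-column spectra as CSV
#'
#' The commented header states the abscissa/intensity units, channel and
#' timestamp; reading a spectrum with an unsorted abscissa is rejected.
#'
#' @param spectrum A `spectrum`.
#' @param path CSV path.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   the `spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  meta <- list(format = "ndfenton spectrum v1",
               abscissa_unit = attr(spectrum, "abscissa_unit"),
               intensity_unit = attr(spectrum, "intensity_unit"),
               channel = attr(spectrum, "channel"),
               time_min = attr(spectrum, "time_min"))
  write_header(path, meta, as.data.frame(spectrum))
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  parsed <- read_commented_csv(path)
  if (!all(c("abscissa", "intensity") %in% names(parsed$data)))
    abort(sprintf("'%s': expected columns abscissa, intensity.", path))
  if (is.unsorted(parsed$data$abscissa, strictly = TRUE))
    abort(sprintf("'%s': abscissa must be strictly increasing.", path))
  new_spectrum(parsed$data$abscissa, parsed$data$intensity,
               abscissa_unit = parsed$meta$abscissa_unit %||% "nm",
               intensity_unit = parsed$meta$intensity_unit %||% "a.u.",
               time_min = num_or_na(parsed$meta$time_min %||% NA),
               channel = parsed$meta$channel %||% "uvvis")
}

#' Write / read time-stamped scalar traces as CSV
#'
#' @param trace A `scalar_trace`.
#' @param path CSV path.
#' @return `write_scalar_trace()` returns `path` invisibly;
#'   `read_scalar_trace()` the `scalar_trace`.
#' @export
write_scalar_trace <- function(trace, path) {
  stopifnot(inherits(trace, "scalar_trace"))
  meta <- list(format = "ndfenton scalar trace v1",
               unit = attr(trace, "unit"),
               addition_min = attr(trace, "addition_min"))
  write_header(path, meta, as.data.frame(trace))
  invisible(path)
}

#' @rdname write_scalar_trace
#' @export
read_scalar_trace <- function(path) {
  parsed <- read_commented_csv(path)
  if (!all(c("time_min", "value") %in% names(parsed$data)))
    abort(sprintf("'%s': expected columns time_min, value.", path))
  new_scalar_trace(parsed$data$time_min, parsed$data$value,
                   unit = parsed$meta$unit %||% "absorbance",
                   addition_min = num_or_na(parsed$meta$addition_min %||% NA))
}

#' Write / read a kinetic trajectory as tidy CSV
#'
#' Long format: `time_s`, `species`, `concentration_M`.
#'
#' @param traj A `kinetic_trajectory`.
#' @param path CSV path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  rates <- attr(traj, "rates")
  meta <- list(format = "ndfenton trajectory v1",
               units = "time_s in seconds; concentration_M in molar",
               rates = paste(names(unclass(rates)), format(as.numeric(rates), digits = 17),
                             sep = "=", collapse = " "))
  write_header(path, meta, as.data.frame(tidy(traj)))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  parsed <- read_commented_csv(path)
  need <- c("time_s", "species", "concentration_M")
  if (!all(need %in% names(parsed$data)))
    abort(sprintf("'%s': expected columns %s.", path, toString(need)))
  wide <- tidyr::pivot_wider(parsed$data, names_from = "species",
                             values_from = "concentration_M")
  wide <- wide[order(wide$time_s), c("time_s", fenton_species())]
  rates <- NULL
  if (!is.null(parsed$meta$rates)) {
    kv <- strsplit(strsplit(parsed$meta$rates, "\\s+")[[1]], "=")
    vals <- as.numeric(vapply(kv, `[`, "", 2))
    names(vals) <- vapply(kv, `[`, "", 1)
    rates <- do.call(rate_constants, as.list(vals))
  }
  structure(tibble::as_tibble(wide), rates = rates, method = "file",
            class = c("kinetic_trajectory", class(tibble::as_tibble(wide))))
}

#' Serialize calibrations and summaries to JSON
#'
#' Calibration objects round-trip through JSON with nodes, means, SDs,
#' replicate counts, model kind and range.
#'
#' @param calib A `t1_calibration` or `fluor_calibration`.
#' @param path JSON path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` the calibration object.
#' @export
write_calibration <- function(calib, path) {
  if (inherits(calib, "t1_calibration")) {
    payload <- list(kind = "t1", model = "hyman spline in log10(c + eps)",
                    levels = calib$levels, eps = calib$eps,
                    monotone = calib$monotone, invertible = calib$invertible)
  } else if (inherits(calib, "fluor_calibration")) {
    payload <- list(kind = "fluorescence", model = "ordinary least squares",
                    slope = calib$slope, intercept = calib$intercept,
                    r_squared = calib$r_squared,
                    conc_range = calib$conc_range,
                    intensity_range = calib$intensity_range, n = calib$n)
  } else abort("unsupported calibration object.")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(payload$kind, "t1")) {
    structure(list(levels = tibble::as_tibble(payload$levels),
                   eps = payload$eps, monotone = payload$monotone,
                   invertible = payload$invertible),
              class = "t1_calibration")
  } else if (identical(payload$kind, "fluorescence")) {
    structure(list(slope = payload$slope, intercept = payload$intercept,
                   r_squared = payload$r_squared,
                   conc_range = payload$conc_range,
                   intensity_range = payload$intensity_range, n = payload$n),
              class = "fluor_calibration")
  } else abort(sprintf("'%s': unknown calibration kind.", path))
}

#' Write / read a run configuration as JSON
#'
#' Every default is written out explicitly so the file is a complete record
#' of the run.
#'
#' @param config A [run_config()].
#' @param path JSON path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}
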