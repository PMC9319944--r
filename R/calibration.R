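#' Build a T1-versus-copper calibration curve
#'
#' Aggregates replicate fitted T1 values per concentration level into means
#' and standard deviations, then fits a shape-preserving monotone (Hyman
#' spline) interpolant in pseudo-log concentration. Concentrations span
#' several decades (the measured ladder runs from blank through 100 nM up to
#' 1 mM), so interpolation is performed on `log10(c + eps)` with
#' `eps = min nonzero concentration / 100` acting as the pseudo-log origin
#' for the blank.
#'
#' A mean sequence that is not strictly decreasing with concentration is
#' flagged (`monotone = FALSE`) and the calibration marked non-invertible;
#' it is never silently reordered.
#'
#' @param data Tibble with `concentration_M` and `t1_us` (replicates as
#'   rows). At least 3 levels, including a blank, are required.
#' @return A `t1_calibration` list: `levels` (per-level tibble with
#'   `concentration_M`, `mean_t1_us`, `sd_t1_us`, `n`), `eps`, `monotone`,
#'   `invertible`.
#' @export
build_t1_calibration <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration_M", "t1_us") %in% names(data)))
  if (any(data$concentration_M < 0)) abort("concentrations must be >= 0.")
  lev <- dplyr::summarise(
    dplyr::group_by(data, concentration_M = .data$concentration_M),
    mean_t1_us = mean(.data$t1_us),
    sd_t1_us = ifelse(dplyr::n() > 1, sd(.data$t1_us), 0),
    n = dplyr::n(), .groups = "drop")
  lev <- dplyr::arrange(lev, .data$concentration_M)
  if (nrow(lev) < 3L) abort("at least 3 distinct concentration levels are required.")
  if (anyDuplicated(data$concentration_M) && is.unsorted(data$concentration_M))
    warn("unsorted duplicate concentration levels were merged per level.")
  nz <- lev$concentration_M[lev$concentration_M > 0]
  if (!length(nz)) abort("calibration needs at least one nonzero level.")
  eps <- min(nz) / 100
  mono <- all(diff(lev$mean_t1_us) < 0)
  if (!mono)
    warn("mean T1 is not strictly decreasing with concentration; calibration flagged non-invertible.")
  structure(list(levels = lev, eps = eps, monotone = mono,
                 invertible = mono && diff(range(lev$mean_t1_us)) > 0),
            class = "t1_calibration")
}

# Rebuild the monotone interpolant (splinefun is not serializable).
t1_calibration_fun <- function(calib) {
  x <- log10(calib$levels$concentration_M + calib$eps)
  splinefun(x, calib$levels$mean_t1_us, method = "hyman")
}

#' Predict mean T1 at given concentrations from a calibration
#'
#' @param calib A `t1_calibration`.
#' @param concentration_M Concentrations inside the calibrated range.
#' @return Predicted mean T1 (us).
#' @export
predict_t1 <- function(calib, concentration_M) {
  stopifnot(inherits(calib, "t1_calibration"))
  rng <- range(calib$levels$concentration_M)
  if (any(concentration_M < rng[1] - 1e-15) || any(concentration_M > rng[2] * (1 + 1e-12)))
    abort("concentration outside the calibrated range.")
  t1_calibration_fun(calib)(log10(concentration_M + calib$eps))
}

#' Invert a T1 calibration to a copper concentration
#'
#' Finds the unique concentration whose calibrated mean T1 equals the
#' measured value, via root finding on the monotone interpolant. The
#' uncertainty interval propagates the per-level T1 standard deviation
#' (interpolated to the working point) through the same inversion.
#'
#' Because copper adsorbs to the diamond surface, measuring a high
#' concentration before a lower one biases the lower reading (carry-over).
#' When `sequence = TRUE` the measured T1 values are treated as consecutive
#' measurements on one particle and the inversion refuses, with an
#' explanatory error, any sequence in which an inferred concentration
#' decreases, unless `allow_carryover = TRUE`.
#'
#' @param calib An invertible `t1_calibration`.
#' @param t1_us Measured T1 value(s) in us, within the calibrated response
#'   range (no extrapolation is performed).
#' @param sequence Treat `t1_us` as an ordered measurement sequence and
#'   apply the carry-over guard.
#' @param allow_carryover Override the carry-over guard.
#' @return Tibble with `t1_us`, `concentration_M`, `lower_M`, `upper_M`.
#' @export
invert_t1 <- function(calib, t1_us, sequence = FALSE, allow_carryover = FALSE) {
  stopifnot(inherits(calib, "t1_calibration"))
  if (!calib$invertible)
    abort("calibration is not invertible (non-monotone or flat mean T1).")
  lev <- calib$levels
  f <- t1_calibration_fun(calib)
  xr <- log10(range(lev$concentration_M) + calib$eps)
  t1r <- range(lev$mean_t1_us)
  tol <- 1e-9 * diff(t1r)
  invert_one <- function(t1) {
    if (t1 > t1r[2] + tol || t1 < t1r[1] - tol)
      abort(sprintf("T1 = %.4g us is outside the calibrated response range [%.4g, %.4g] us; refusing to extrapolate.",
                    t1, t1r[1], t1r[2]))
    t1 <- min(max(t1, t1r[1]), t1r[2])
    if (t1 >= lev$mean_t1_us[1]) return(lev$concentration_M[1])
    if (t1 <= lev$mean_t1_us[nrow(lev)]) return(lev$concentration_M[nrow(lev)])
    x <- uniroot(function(z) f(z) - t1, interval = xr, tol = 1e-13)$root
    10^x - calib$eps
  }
  conc <- vapply(t1_us, invert_one, numeric(1))
  conc <- pmax(conc, 0)
  if (sequence && !allow_carryover && length(conc) > 1L &&
      any(diff(conc) < -1e-12)) {
    abort(paste0(
      "measurement sequence runs from high to low concentration; copper ",
      "carry-over on the diamond surface makes such readings unreliable. ",
      "Set `allow_carryover = TRUE` to override."))
  }
  sd_at <- approx(lev$concentration_M, lev$sd_t1_us, xout = conc, rule = 2)$y
  lo <- vapply(pmin(pmax(t1_us - sd_at, t1r[1]), t1r[2]), invert_one, numeric(1))
  hi <- vapply(pmin(pmax(t1_us + sd_at, t1r[1]), t1r[2]), invert_one, numeric(1))
  tibble::tibble(t1_us = as.numeric(t1_us), concentration_M = conc,
                 lower_M = pmin(lo, hi), upper_M = pmax(lo, hi))
}

#' Estimate the limit of detection of the T1 calibration
#'
#' Three-sigma decision rule: the LOD is the smallest concentration whose
#' calibrated mean response differs from the blank mean by at least three
#' blank standard deviations. With a zero blank SD the smallest calibrated
#' nonzero level is returned with a warning.
#'
#' @param calib An invertible `t1_calibration`.
#' @param blank_t1_us Replicate blank (water) T1 measurements (us).
#' @return LOD concentration (molar).
#' @export
estimate_lod <- function(calib, blank_t1_us) {
  stopifnot(inherits(calib, "t1_calibration"))
  if (!calib$invertible) abort("calibration is not invertible.")
  m <- mean(blank_t1_us)
  s <- if (length(blank_t1_us) > 1L) sd(blank_t1_us) else 0
  lev <- calib$levels
  nz_min <- min(lev$concentration_M[lev$concentration_M > 0])
  if (s == 0) {
    warn("zero blank SD: returning the smallest calibrated nonzero level.")
    return(nz_min)
  }
  target <- m - 3 * s
  f <- t1_calibration_fun(calib)
  xr <- log10(range(lev$concentration_M) + calib$eps)
  if (f(xr[2]) > target)
    abort("no calibrated concentration differs from blank by 3 SD.")
  if (f(xr[1]) <= target) return(lev$concentration_M[1])
  x <- uniroot(function(z) f(z) - target, interval = xr, tol = 1e-13)$root
  max(10^x - calib$eps, 0)
}

#' Fit the HTA fluorescence calibration line
#'
#' Ordinary least squares of 420 nm emission intensity on HTA concentration.
#'
#' @param data Tibble with `concentration_M` and `intensity` (>= 2 points).
#' @return A `fluor_calibration` list: `slope` (a.u. per M), `intercept`,
#'   `r_squared`, `conc_range`, `intensity_range`, `n`.
#' @export
fit_fluorescence_calibration <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration_M", "intensity") %in% names(data)))
  if (nrow(data) < 2L) abort("at least 2 calibration points are required.")
  fit <- lm(intensity ~ concentration_M, data = data)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    abort("calibration slope must be positive over the calibrated range.")
  r2 <- if (nrow(data) > 2L) suppressWarnings(summary(fit)$r.squared) else 1
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 conc_range = range(data$concentration_M),
                 intensity_range = range(predict(fit)),
                 n = nrow(data)),
            class = "fluor_calibration")
}

#' @export
glance.fluor_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' Quantify hydroxyl radical from a reaction spectrum intensity
#'
#' Inverts the HTA dosimeter calibration: the hydroxyl-radical concentration
#' trapped as HTA is `(intensity - intercept) / slope`. Affine-equivariant:
#' rescaling calibration and reaction intensities by a common factor leaves
#' the estimate unchanged.
#'
#' @param calib A `fluor_calibration`.
#' @param intensity 420 nm emission intensity of the reaction spectrum;
#'   must lie within the calibrated intensity range.
#' @return Hydroxyl-radical concentration in uM.
#' @export
quantify_oh <- function(calib, intensity) {
  stopifnot(inherits(calib, "fluor_calibration"))
  rng <- calib$intensity_range
  tol <- 1e-9 * max(abs(rng), 1)
  if (any(intensity < rng[1] - tol) || any(intensity > rng[2] + tol))
    abort(sprintf("intensity outside the calibrated range [%.4g, %.4g].",
                  rng[1], rng[2]))
  1e6 * (intensity - calib$intercept) / calib$slope
}
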