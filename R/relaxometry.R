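#' Fit the bi-exponential relaxation model
#'
#' Fits `PL(tau) = I_inf + C_a exp(-tau/T_a) + C_b exp(-tau/T_b)` by
#' least squares with non-negative amplitudes and the component ordering
#' `T_a <= T_b` enforced by relabelling (the model is symmetric in its two
#' components). The long component `T_b` is reported as "the T1", the part of
#' the ensemble found to track paramagnetic concentration.
#'
#' Initialization uses a log-slope heuristic: the offset is estimated from the
#' longest dark times, the long component from the log-linear slope of the
#' offset-subtracted tail, and the short component from the residual head.
#' Optimization runs `nls` (`port`, bounded below at zero) and falls back to
#' Nelder-Mead on the residual sum of squares; an unconverged fit is flagged,
#' not an error. If the short amplitude collapses to zero the short time
#' constant is reported as `NA` and `reported_t1` remains the long component.
#'
#' @param curve A `relaxation_curve` (or tibble with `tau_us`, `pl`);
#'   at least 6 distinct dark times are required.
#' @param weighted Use inverse-variance (Poisson, `1/max(pl, 1)`) weights;
#'   default is unweighted, counts being large.
#' @return A `biexp_fit` list: `estimate` (named vector `I_inf`, `C_a`,
#'   `T_a`, `C_b`, `T_b`), `reported_t1`, `converged`, `resid_norm`,
#'   `n_points`.
#' @export
fit_biexponential <- function(curve, weighted = FALSE) {
  stopifnot(is.data.frame(curve), all(c("tau_us", "pl") %in% names(curve)))
  tau <- as.numeric(curve$tau_us); pl <- as.numeric(curve$pl)
  if (length(unique(tau)) < 6L)
    abort("at least 6 distinct dark times are required for a 5-parameter fit.")
  w <- if (weighted) 1 / pmax(pl, 1) else rep(1, length(pl))

  init <- biexp_init(tau, pl)
  model <- function(p, tau) {
    p[["I_inf"]] + p[["C_a"]] * exp(-tau / p[["T_a"]]) +
      p[["C_b"]] * exp(-tau / p[["T_b"]])
  }
  rss <- function(p) sum(w * (pl - model(as.list(p), tau))^2)

  est <- NULL; converged <- FALSE
  fit <- tryCatch(
    suppressWarnings(nls(pl ~ I_inf + C_a * exp(-tau / T_a) + C_b * exp(-tau / T_b),
        data = data.frame(tau = tau, pl = pl),
        start = as.list(init), weights = w,
        algorithm = "port",
        lower = c(I_inf = 0, C_a = 0, T_a = 1e-6, C_b = 0, T_b = 1e-6),
        control = nls.control(maxiter = 500, tol = 1e-10, warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- coef(fit)
    converged <- fit$convInfo$isConv %||% FALSE
  }
  # fall back / polish with Nelder-Mead on the sum of squares
  if (is.null(est) || !converged || rss(est) > rss(init) + 1e-9) {
    start <- if (is.null(est)) init else est
    nm <- optim(start, rss, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(est) || nm$value < rss(est)) {
      est <- nm$par
      converged <- nm$convergence == 0
    }
  }
  est <- pmax(est, c(0, 0, 1e-9, 0, 1e-9))
  # enforce T_a <= T_b by relabelling the symmetric components
  if (est[["T_a"]] > est[["T_b"]])
    est[c("C_a", "T_a", "C_b", "T_b")] <- est[c("C_b", "T_b", "C_a", "T_a")]
  t_a <- est[["T_a"]]
  if (est[["C_a"]] < 1e-9 * max(est[["C_b"]], 1)) t_a <- NA_real_
  structure(list(
    estimate = c(I_inf = est[["I_inf"]], C_a = est[["C_a"]], T_a = t_a,
                 C_b = est[["C_b"]], T_b = est[["T_b"]]),
    reported_t1 = est[["T_b"]],
    converged = isTRUE(converged),
    resid_norm = sqrt(rss(est)),
    n_points = length(tau)
  ), class = "biexp_fit")
}

# Log-slope initialization for the bi-exponential fit.
biexp_init <- function(tau, pl) {
  ord <- order(tau); tau <- tau[ord]; pl <- pl[ord]
  n <- length(tau)
  i_inf <- min(mean(pl[tau >= tau[n] / 5]), min(pl))
  y <- pmax(pl - i_inf, max(pl) * 1e-9)
  mid <- exp(mean(log(range(tau))))
  tail_idx <- which(tau >= mid & y > 0)
  if (length(tail_idx) < 2L) tail_idx <- seq(max(1, n - 3), n)
  ft <- lm(log(y[tail_idx]) ~ tau[tail_idx])
  t_b <- -1 / min(unname(coef(ft)[2]), -1e-6)
  c_b <- exp(unname(coef(ft)[1]))
  head_res <- pmax(y - c_b * exp(-tau / t_b), max(y) * 1e-9)
  head_idx <- which(tau < mid)
  if (length(head_idx) < 2L) head_idx <- seq_len(min(4, n))
  fh <- lm(log(head_res[head_idx]) ~ tau[head_idx])
  t_a <- -1 / min(unname(coef(fh)[2]), -1e-6)
  c_a <- exp(unname(coef(fh)[1]))
  if (!is.finite(t_a) || t_a <= 0 || t_a > t_b) t_a <- t_b / 20
  if (!is.finite(c_a) || c_a <= 0) c_a <- c_b / 3
  c(I_inf = max(i_inf, 0), C_a = c_a, T_a = t_a, C_b = max(c_b, 1e-9),
    T_b = max(t_b, 1e-6))
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("Bi-exponential relaxation fit\n")
  print(round(x$estimate, 4))
  cat(sprintf("reported T1 (long component): %.3f us; converged: %s\n",
              x$reported_t1, x$converged))
  invisible(x)
}

#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(reported_t1_us = x$reported_t1, converged = x$converged,
                 resid_norm = x$resid_norm, n_points = x$n_points)
}

#' Quality-control particle records
#'
#' Applies the selection rules used during acquisition and analysis: particle
#' brightness must lie within the stated counts-per-second bounds (the upper
#' bound operationalizes the exclusion of obvious aggregates) and fitted T1
#' must not exceed the cutoff (values above it are attributed to dirt,
#' outlier particles or fitting errors).
#'
#' @param particles Tibble with columns `id`, `cps` and `t1_us`.
#' @param intensity_bounds Lower/upper counts-per-second bounds
#'   (default `c(1e6, 1e7)`).
#' @param t1_cutoff_us Maximum acceptable T1 (default 600 us).
#' @return The input with a `qc_status` column (`kept`,
#'   `excluded_intensity`, `excluded_aggregate`, `excluded_t1`) and a
#'   `qc_reason` column; every input row appears exactly once.
#' @export
qc_particles <- function(particles, intensity_bounds = c(1e6, 1e7),
                         t1_cutoff_us = 600) {
  stopifnot(is.data.frame(particles),
            all(c("id", "cps", "t1_us") %in% names(particles)))
  status <- dplyr::case_when(
    particles$cps < intensity_bounds[1] ~ "excluded_intensity",
    particles$cps > intensity_bounds[2] ~ "excluded_aggregate",
    particles$t1_us > t1_cutoff_us ~ "excluded_t1",
    TRUE ~ "kept"
  )
  reason <- dplyr::case_when(
    status == "excluded_intensity" ~
      sprintf("brightness %.3g cps below %.0e cps", particles$cps, intensity_bounds[1]),
    status == "excluded_aggregate" ~
      sprintf("brightness %.3g cps above %.0e cps (aggregate)", particles$cps, intensity_bounds[2]),
    status == "excluded_t1" ~
      sprintf("T1 %.3g us above %.0f us cutoff", particles$t1_us, t1_cutoff_us),
    TRUE ~ ""
  )
  out <- tibble::add_column(tibble::as_tibble(particles),
                            qc_status = status, qc_reason = reason)
  if (!any(status == "kept"))
    warn("quality control excluded every particle.")
  out
}

#' Time-resolve T1 with the moving-window method
#'
#' Overlapping blocks of repetitions are each pooled and fitted separately so
#' that one 10-minute acquisition yields a T1 time series: repetitions
#' 1..window_len form the first point, 1+stride .. window_len+stride the
#' second, and so on until the last window ends at the final repetition.
#' The window/stride defaults reproduce the published scheme (2500-repetition
#' windows advanced by 100, i.e. 76 windows for a 10,000-repetition record).
#'
#' @param record A `photon_count_record`.
#' @param window_len Window length in repetitions.
#' @param stride Window advance in repetitions.
#' @param window,weighted Passed to [integrate_window()] /
#'   [fit_biexponential()].
#' @return A `t1_series`: tibble with `window_index`, `rep_start`,
#'   `rep_end`, `time_min` (wall-clock window midpoint), `t1_us`,
#'   `converged`.
#' @export
moving_window_series <- function(record, window_len = 2500L, stride = 100L,
                                 window = NULL, weighted = FALSE) {
  stopifnot(inherits(record, "photon_count_record"))
  pulse <- attr(record, "pulse")
  n <- pulse$n_reps
  window_len <- as.integer(window_len); stride <- as.integer(stride)
  if (window_len > n) abort("`window_len` exceeds the number of repetitions.")
  if (stride < 1L) abort("`stride` must be >= 1.")
  if ((n - window_len) %% stride != 0L)
    warn("(n_reps - window_len) is not a multiple of `stride`; the last window still ends at the final repetition.")
  starts <- unique(c(seq(1L, n - window_len + 1L, by = stride),
                     n - window_len + 1L))
  res <- purrr::map(starts, function(s) {
    fit <- fit_biexponential(
      integrate_window(record, window = window, span = c(s, s + window_len - 1L)),
      weighted = weighted)
    tibble::tibble(rep_start = s, rep_end = s + window_len - 1L,
                   t1_us = fit$reported_t1, converged = fit$converged)
  })
  out <- dplyr::bind_rows(res)
  out <- tibble::add_column(out, window_index = seq_len(nrow(out)), .before = 1)
  out$time_min <- (out$rep_start + out$rep_end - 1) / 2 / n * pulse$acquisition_min
  structure(out, window_len = window_len, stride = stride,
            class = c("t1_series", class(out)))
}

#' Flag outliers with the interquartile-range rule
#'
#' Tukey's rule with linear-interpolation quartiles (R quantile type 7):
#' values outside `[Q1 - factor * IQR, Q3 + factor * IQR]` are flagged.
#' When the IQR is exactly zero only values different from the median are
#' flagged. With fewer than 4 points nothing is flagged and a warning is
#' issued. Flagged points are meant to be excluded from downstream averages.
#'
#' @param series A `t1_series` (or tibble with a `t1_us` column), or a bare
#'   numeric vector.
#' @param factor Tukey multiplier (default 1.5).
#' @return The series with a logical `outlier` column (or, for a numeric
#'   input, a logical vector).
#' @export
iqr_filter <- function(series, factor = 1.5) {
  values <- if (is.data.frame(series)) series$t1_us else as.numeric(series)
  if (length(values) < 4L) {
    warn("fewer than 4 points: no outlier flagging performed.")
    flag <- rep(FALSE, length(values))
  } else {
    q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    flag <- if (iqr == 0) values != median(values)
    else values < q[1] - factor * iqr | values > q[2] + factor * iqr
  }
  if (is.data.frame(series)) {
    series$outlier <- flag
    series
  } else flag
}

#' Normalize T1 values to the ultrapure-water baseline
#'
#' @param values T1 values (us).
#' @param baseline Replicate blank (ultrapure water) T1 measurements (us).
#' @return Numeric vector: `100 * values / mean(baseline)` (percent of
#'   baseline), with the propagated relative dispersion (baseline
#'   standard error combined with the value spread, in percent points)
#'   as attribute `dispersion_pct`.
#' @export
normalize_t1 <- function(values, baseline) {
  if (length(baseline) < 1L || mean(baseline) <= 0)
    abort("baseline mean must be > 0.")
  m <- mean(baseline)
  out <- 100 * values / m
  rel_b <- if (length(baseline) > 1L) sd(baseline) / sqrt(length(baseline)) / m else 0
  rel_v <- if (length(values) > 1L) sd(values) / sqrt(length(values)) / mean(values) else 0
  attr(out, "dispersion_pct") <- 100 * sqrt(rel_b^2 + rel_v^2) *
    abs(mean(values) / m)
  out
}
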