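test_that("noiseless bi-exponential curves are recovered on a parameter grid", {
  tau <- pulse_config()$tau_us
  grid <- expand.grid(T_b = seq(50, 600, length.out = 5), T_a = c(1, 8, 15, 30))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    truth <- c(I_inf = 1000, C_a = 300, T_a = grid$T_a[i], C_b = 700,
               T_b = grid$T_b[i])
    pl <- truth[["I_inf"]] + truth[["C_a"]] * exp(-tau / truth[["T_a"]]) +
      truth[["C_b"]] * exp(-tau / truth[["T_b"]])
    fit <- fit_biexponential(new_relaxation_curve(tau, pl))
    rel <- max(abs(fit$estimate - truth) / truth)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("single-exponential input is handled degenerately but safely", {
  tau <- pulse_config()$tau_us
  pl <- 500 + 800 * exp(-tau / 120)
  fit <- fit_biexponential(new_relaxation_curve(tau, pl))
  # the nested single-exponential model must be recovered: the long
  # component matches the generating constant and the curve is reproduced
  expect_equal(fit$reported_t1, 120, tolerance = 1e-4)
  expect_lt(fit$resid_norm / max(pl), 1e-6)
  # either the short component collapses (T_a undefined by convention) or
  # both components coincide at the generating constant
  e <- fit$estimate
  expect_true(is.na(e[["T_a"]]) || e[["C_a"]] < 1e-6 * e[["C_b"]] ||
                abs(e[["T_a"]] - 120) < 1)
})

test_that("the fit requires enough distinct dark times", {
  expect_error(fit_biexponential(new_relaxation_curve(c(1, 2, 3, 4, 5),
                                                      rep(10, 5))),
               "at least 6")
})

test_that("Poisson-noised records recover the generating T1 within 5%", {
  t1s <- vapply(1:10, function(sd) fitted_t1(300, seed = sd), numeric(1))
  expect_lt(abs(median(t1s) - 300) / 300, 0.05)
})

test_that("moving window spans follow the published scheme", {
  p <- fast_pulse(10000L)
  rec <- generate_photon_counts(300, p, seed = 1, noise = FALSE)
  ser <- moving_window_series(rec, window_len = 2500L, stride = 100L)
  expect_identical(nrow(ser), 76L)
  expect_identical(ser$rep_start[1], 1L)
  expect_identical(ser$rep_end[1], 2500L)
  expect_identical(ser$rep_start[76], 7501L)
  expect_identical(ser$rep_end[76], 10000L)
  expect_true(all(ser$rep_end - ser$rep_start + 1L == 2500L))
  # stationary noiseless record: every window fits the same T1
  expect_lt(diff(range(ser$t1_us)) / median(ser$t1_us), 1e-6)
})

test_that("N = window_len collapses to a single window", {
  p <- fast_pulse(500L)
  rec <- generate_photon_counts(200, p, seed = 2)
  ser <- moving_window_series(rec, window_len = 500L, stride = 100L)
  expect_identical(nrow(ser), 1L)
  expect_error(moving_window_series(rec, window_len = 600L), "exceeds")
})

test_that("moving-window mean matches the full-record fit on a stationary record", {
  p <- fast_pulse(4000L)
  rec <- generate_photon_counts(250, p, seed = 9)
  full <- fit_biexponential(integrate_window(rec))$reported_t1
  ser <- moving_window_series(rec, window_len = 1000L, stride = 500L)
  se <- sd(ser$t1_us) / sqrt(nrow(ser))
  expect_lt(abs(mean(ser$t1_us) - full), 2 * max(se, 0.5))
})

test_that("IQR filter flags gross outliers and is idempotent on kept points", {
  x <- c(100, 102, 98, 101, 500)
  flags <- iqr_filter(x)
  expect_identical(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(iqr_filter(x[!flags]), rep(FALSE, 4))
  # all-equal series: nothing flagged under the IQR = 0 convention
  expect_identical(iqr_filter(rep(7, 6)), rep(FALSE, 6))
  # IQR = 0 with a deviating value: only values != median flagged
  expect_identical(iqr_filter(c(5, 5, 5, 5, 9)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_warning(out <- iqr_filter(c(1, 2, 3)), "fewer than 4")
  expect_identical(out, rep(FALSE, 3))
  # data-frame interface adds a flag column
  ser <- tibble::tibble(t1_us = x)
  expect_identical(iqr_filter(ser)$outlier, flags)
})

test_that("quality control labels every particle exactly once", {
  particles <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    cps = c(5e6, 1e5, 5e8, 2e6),
    t1_us = c(200, 200, 200, 700))
  out <- qc_particles(particles)
  expect_identical(out$qc_status,
                   c("kept", "excluded_intensity", "excluded_aggregate",
                     "excluded_t1"))
  expect_identical(nrow(out), nrow(particles))
  expect_true(all(out$qc_reason[out$qc_status != "kept"] != ""))
  expect_warning(qc_particles(particles[2, ]), "every particle")
})

test_that("T1 normalization to the water baseline is percent of the mean", {
  expect_equal(as.numeric(normalize_t1(300, c(300, 300))), 100)
  expect_equal(as.numeric(normalize_t1(150, 300)), 50)
  expect_equal(as.numeric(normalize_t1(150, c(290, 310))), 50)
  expect_error(normalize_t1(100, c(-1, 1)), "> 0")
})

test_that("fitted T1 decreases monotonically along the copper ladder", {
  ladder <- c(0, 1e-7, 1e-5, 1e-4, 5e-4, 1e-3)
  p <- fast_pulse(2000L)
  med <- vapply(ladder, function(conc) {
    median(vapply(1:5, function(sd)
      fitted_t1(t1_for_cu(conc), seed = 31 * sd + round(1e9 * conc),
                pulse = p), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
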