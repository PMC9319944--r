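test_that("relaxivity model maps concentrations to T1 as stated", {
  s <- sensor_params()
  traj0 <- simulate_kinetics(initial_state(cu2 = 0, h2o2 = 0, th = 0),
                             rate_constants(), t_grid = c(0, 1))
  expect_equal(trajectory_to_t1(traj0, s)$t1_us, rep(1e6 / s$r0, 2))

  # rate increase is linear in copper: doubling [Cu2+] doubles the increment
  s0 <- sensor_params(r_oh = 0, r_o2m = 0)
  t1_of <- function(c) {
    tr <- simulate_kinetics(initial_state(cu2 = c, h2o2 = 0, th = 0),
                            rate_constants(), t_grid = c(0, 1))
    trajectory_to_t1(tr, s0)$rate_per_s[1] - s0$r0
  }
  expect_equal(t1_of(2e-4) / t1_of(1e-4), 2, tolerance = 1e-9)

  # arithmetic: R0 = 1/(300 us), r * c = 1/(300 us)  ->  T1 = 150 us
  s2 <- sensor_params(r0 = 1 / 300e-6, r_cu2 = (1 / 300e-6) / 1e-3,
                      r_oh = 0, r_o2m = 0)
  tr <- simulate_kinetics(initial_state(cu2 = 1e-3, h2o2 = 0, th = 0),
                          rate_constants(), t_grid = c(0, 1))
  expect_equal(trajectory_to_t1(tr, s2)$t1_us[1], 150)
})

test_that("pulse configuration enforces the stated dark-time range", {
  p <- pulse_config()
  expect_length(p$tau_us, 21L)
  expect_equal(range(p$tau_us), c(0.2, 1e4), tolerance = 1e-9)
  expect_error(pulse_config(tau_us = c(0.1, 1, 10)), "0.2")
  expect_error(pulse_config(tau_us = c(5, 1)), "increasing")
})

test_that("noiseless photon counts equal the rounded Eq.-1 mean curve", {
  p <- fast_pulse(50L); s <- sensor_params()
  rec <- generate_photon_counts(250, p, s, noise = FALSE)
  mu <- biexp_mean(p$tau_us, 250, s)
  cmat <- matrix(rec$counts, nrow = 50, byrow = TRUE)
  expect_identical(cmat[1, ], as.integer(round(mu)))
  expect_true(all(apply(cmat, 1, identical, cmat[1, ])))
  expect_true(all(rec$counts >= 0))
})

test_that("records are seeded and byte-identical under the same seed", {
  p <- fast_pulse(100L)
  a <- generate_photon_counts(300, p, seed = 11)
  b <- generate_photon_counts(300, p, seed = 11)
  c <- generate_photon_counts(300, p, seed = 12)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, c$counts))
})

test_that("repetition means follow the Eq.-1 curve within 3 standard errors", {
  p <- pulse_config()  # 10,000 repetitions
  s <- sensor_params()
  rec <- generate_photon_counts(300, p, s, seed = 5)
  m <- tapply(rec$counts, rec$tau_us, mean)
  mu <- biexp_mean(sort(unique(rec$tau_us)), 300, s)
  se <- sqrt(mu / p$n_reps)
  expect_true(all(abs(m - mu) <= 3 * se))
})

test_that("photon generator validates its inputs", {
  expect_error(generate_photon_counts(-5), "positive")
  expect_error(generate_photon_counts(300, sensor = sensor_params(photon_yield = 1)),
               NA)
  expect_error(sensor_params(photon_yield = 0), "> 0")
  expect_error(sensor_params(f_inf = 0.9), "sum to 1")
})

test_that("detection window search finds a known optimal leading window", {
  # contrast concentrated in the first 1 us (bins of 0.1 us)
  t_us <- seq(0, 0.9, by = 0.1)
  signal <- c(rep(1000, 10))
  reference <- c(rep(600, 5), rep(1000, 5))  # contrast only in bins 1..5
  win <- determine_detection_window(
    tibble::tibble(t_us = t_us, signal = signal, reference = reference))
  expect_identical(win$start, 1L)
  expect_identical(win$length, 5L)
  expect_equal(win$length_us, 0.5)

  # ties go to the earliest window of a given length
  sig2 <- c(10, 0, 10, 0); ref2 <- c(0, 0, 0, 0)
  win2 <- determine_detection_window(
    tibble::tibble(t_us = 1:4, signal = sig2, reference = ref2))
  expect_identical(win2$start, 1L)

  expect_error(determine_detection_window(
    tibble::tibble(t_us = 1:4, signal = rep(0, 4), reference = rep(0, 4))),
    "no contrast")
  expect_error(determine_detection_window(
    tibble::tibble(t_us = 1:4, signal = rep(5, 4), reference = rep(5, 4))),
    "no contrast")
})

test_that("window integration pools counts additively and deterministically", {
  p <- fast_pulse(4L)
  rec <- generate_photon_counts(300, p, seed = 3, time_resolved = TRUE,
                                n_bins = 5L)
  # single repetition with unit counts: PL equals window length in samples
  one <- rec[rec$repetition == 1, ]
  one$counts <- 1L
  attr(one, "pulse") <- attr(rec, "pulse")
  class(one) <- class(rec)
  cv <- integrate_window(one, window = 1:3, span = c(1, 1))
  expect_equal(cv$pl, rep(3, length(p$tau_us)))

  # identical spans give identical curves
  c1 <- integrate_window(rec, window = 1:5, span = c(1, 4))
  c2 <- integrate_window(rec, window = 1:5, span = c(1, 4))
  expect_identical(c1$pl, c2$pl)

  # additivity over disjoint half-spans
  full <- integrate_window(rec, window = 1:5, span = c(1, 4))
  h1 <- integrate_window(rec, window = 1:5, span = c(1, 2))
  h2 <- integrate_window(rec, window = 1:5, span = c(3, 4))
  expect_equal(full$pl, h1$pl + h2$pl)

  expect_error(integrate_window(rec, window = 1:5, span = c(3, 2)), "span")
  expect_error(integrate_window(rec, span = c(1, 2)), "window")
})
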