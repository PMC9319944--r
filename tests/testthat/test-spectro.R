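test_that("kinetic trace extraction is exact at nodes and time-ordered", {
  sps <- purrr::map(c(0, 5, 10), function(tm)
    new_spectrum(seq(700, 900, by = 10), rep(0.5, 21), abscissa_unit = "nm",
                 time_min = tm, channel = "uvvis"))
  tr <- kinetic_trace(sps, 800)
  expect_equal(tr$value, rep(0.5, 3))
  expect_equal(tr$time_min, c(0, 5, 10))
  expect_error(kinetic_trace(sps, 950), "outside")

  # trace at a node equals the stored intensity exactly
  sp <- new_spectrum(c(700, 800, 900), c(1, 2, 3), time_min = 0)
  expect_equal(kinetic_trace(list(sp), 800)$value, 2)

  # synthetic copper decay: trace proportional to [Cu2+](t)
  traj <- simulate_kinetics(t_grid = seq(0, 1200, by = 300))
  sps2 <- purrr::map(seq_len(nrow(traj)), function(i)
    new_spectrum(seq(700, 900, by = 5),
                 12.6 * traj$Cu2[i] * rep(1, 41),
                 time_min = traj$time_s[i] / 60, channel = "uvvis"))
  tr2 <- kinetic_trace(sps2, 800)
  expect_equal(tr2$value / tr2$value[1], traj$Cu2 / traj$Cu2[1])
})

test_that("Beer-Lambert inversion turns an absorbance drop into molar depletion", {
  tr <- new_scalar_trace(c(0, 20), c(0.0126, 0.0126 - 2.52e-3))
  expect_equal(beer_lambert_delta_c(tr, 12.6, 1) * 1e3, 0.2)
  # flat trace: no change
  expect_equal(beer_lambert_delta_c(new_scalar_trace(0:2, rep(0.1, 3))), 0)
  # property: linear in delta-A, inverse in epsilon and path
  set.seed(7)
  for (i in 1:20) {
    dA <- stats::runif(1, 1e-4, 1e-1); eps <- stats::runif(1, 1, 100)
    l <- stats::runif(1, 0.1, 10)
    tr <- new_scalar_trace(c(0, 1), c(2 * dA, dA))
    expect_equal(beer_lambert_delta_c(tr, eps, l), dA / (eps * l))
    expect_equal(beer_lambert_delta_c(tr, eps, 2 * l),
                 beer_lambert_delta_c(tr, eps, l) / 2)
  }
})

test_that("multipoint baseline is exact on linear backgrounds and idempotent", {
  x <- seq(700, 1050, by = 1)
  # pure linear ramp with anchors at both ends vanishes
  ramp <- new_spectrum(x, 2 + 0.01 * x, abscissa_unit = "cm-1",
                       channel = "raman")
  corr <- multipoint_baseline(ramp, c(700, 1050))
  expect_equal(corr$intensity, rep(0, length(x)), tolerance = 1e-12)
  # a spectrum already zero at anchors and linear between is a fixed point
  expect_equal(multipoint_baseline(corr, c(700, 1050))$intensity,
               corr$intensity)
  # Gaussian peak on a cubic background: peak recovered within 1%
  bg <- 50 - 0.02 * (x - 876) + 1e-6 * (x - 876)^2 + 5e-9 * (x - 876)^3
  peak <- 1.0 * exp(-(x - 876)^2 / (2 * 8^2))
  sp <- new_spectrum(x, bg + peak, abscissa_unit = "cm-1", channel = "raman")
  corrected <- multipoint_baseline(sp, c(820, 930))
  expect_equal(peak_intensity(corrected, 876, 30), 1.0, tolerance = 0.01)
  # idempotence with the same anchors
  expect_equal(multipoint_baseline(corrected, c(820, 930))$intensity,
               corrected$intensity)
  expect_error(multipoint_baseline(sp, c(600, 930)), "inside")
  expect_error(multipoint_baseline(sp, 820), "at least two")
})

test_that("peak intensity reads the band maximum in its window", {
  x <- seq(800, 950, by = 1)
  sp <- new_spectrum(x, 0.5 * exp(-(x - 876)^2 / 128), abscissa_unit = "cm-1",
                     channel = "raman")
  expect_equal(peak_intensity(sp, 876, 30), 0.5)
  expect_error(peak_intensity(sp, 400, 10), "outside")
})

test_that("fractional decrease is the stated percentage", {
  expect_equal(fractional_decrease(1, 1), 0)
  expect_equal(fractional_decrease(1.00, 0.97), 3)
  expect_equal(fractional_decrease(1, 0), 100)
  expect_error(fractional_decrease(0, 1), "> 0")
})

test_that("oxygen summary reports baseline, endpoint and liberated amount", {
  flat <- new_scalar_trace(seq(-2, 20, by = 1), rep(5, 23), unit = "mg/L",
                           addition_min = 0)
  s <- o2_summary(flat)
  expect_equal(s$baseline_mgL, 5)
  expect_equal(s$liberated_mgL, 0)
  # a +9 mg/L step gives final - baseline = 9
  step <- new_scalar_trace(seq(-2, 20, by = 1),
                           c(rep(5, 2), rep(14, 21)), unit = "mg/L",
                           addition_min = 0)
  s2 <- o2_summary(step)
  expect_equal(s2$endpoint_mgL - s2$baseline_mgL, 9)
  expect_equal(s2$liberated_mgL, 9)
  no_pre <- new_scalar_trace(seq(0, 20, by = 1), rep(5, 21), unit = "mg/L",
                             addition_min = 0)
  expect_error(o2_summary(no_pre), "before the addition marker")
})
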