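ladder <- c(0, 1e-7, 1e-5, 1e-4, 5e-4, 1e-3)

noiseless_t1_calib <- function(conc = ladder, reps = 2L) {
  t1 <- t1_for_cu(conc)
  build_t1_calibration(tibble::tibble(
    concentration_M = rep(conc, each = reps),
    t1_us = rep(t1, each = reps)))
}

test_that("calibration reproduces the generating T1 exactly at the nodes", {
  cal <- noiseless_t1_calib()
  expect_true(cal$invertible)
  expect_equal(predict_t1(cal, ladder), t1_for_cu(ladder))
})

test_that("flat and non-monotone calibrations are flagged, not fixed", {
  flat <- suppressWarnings(build_t1_calibration(tibble::tibble(
    concentration_M = c(0, 1e-6, 1e-3), t1_us = rep(300, 3))))
  expect_false(flat$invertible)
  expect_error(invert_t1(flat, 300), "not invertible")
  expect_warning(
    bad <- build_t1_calibration(tibble::tibble(
      concentration_M = c(0, 1e-6, 1e-3), t1_us = c(300, 310, 200))),
    "not strictly decreasing")
  expect_false(bad$monotone)
})

test_that("forward-then-invert round trip is exact to 1e-6 relative", {
  cal <- noiseless_t1_calib()
  set.seed(42)
  cs <- 10^stats::runif(50, -7, -3)
  inv <- invert_t1(cal, predict_t1(cal, cs))
  expect_lt(max(abs(inv$concentration_M - cs) / cs), 1e-6)
  # node identities, including the blank
  expect_equal(invert_t1(cal, t1_for_cu(0))$concentration_M, 0)
  expect_equal(invert_t1(cal, t1_for_cu(1e-3))$concentration_M, 1e-3,
               tolerance = 1e-9)
})

test_that("inversion refuses extrapolation and high-to-low sequences", {
  cal <- noiseless_t1_calib()
  expect_error(invert_t1(cal, 350), "outside the calibrated response range")
  expect_error(invert_t1(cal, 10), "outside the calibrated response range")
  t1_seq <- t1_for_cu(c(1e-4, 1e-6))  # high concentration measured first
  expect_error(invert_t1(cal, t1_seq, sequence = TRUE), "carry-over")
  expect_silent(invert_t1(cal, t1_seq, sequence = TRUE,
                          allow_carryover = TRUE))
  expect_silent(invert_t1(cal, rev(t1_seq), sequence = TRUE))
})

test_that("replicate noise propagates into per-level SD at a sane scale", {
  p <- fast_pulse(2000L)
  conc <- c(0, 1e-4, 1e-3)
  reps <- 4L
  dat <- purrr::map_dfr(seq_along(conc), function(i) {
    tibble::tibble(
      concentration_M = conc[i],
      t1_us = vapply(seq_len(reps), function(r)
        fitted_t1(t1_for_cu(conc[i]), seed = 100 * i + r, pulse = p),
        numeric(1)))
  })
  cal <- build_t1_calibration(dat)
  # reference dispersion from a larger independent simulation at the blank
  ref <- sd(vapply(1:12, function(r)
    fitted_t1(t1_for_cu(0), seed = 9000 + r, pulse = p), numeric(1)))
  expect_lt(cal$levels$sd_t1_us[1], 3 * ref + 1e-9)
  expect_true(all(cal$levels$n == reps))
})

test_that("limit of detection follows the 3-sigma rule", {
  cal <- noiseless_t1_calib()
  expect_warning(lod0 <- estimate_lod(cal, rep(300, 4)), "zero blank SD")
  expect_equal(lod0, 1e-7)
  # smaller blank SD -> smaller LOD
  lod_small <- estimate_lod(cal, c(299.9, 300.1, 300, 300))
  lod_big <- estimate_lod(cal, c(297, 303, 300, 300))
  expect_lt(lod_small, lod_big)
  # and the decision threshold is exactly 3 SD below the blank mean
  expect_equal(predict_t1(cal, lod_small),
               mean(c(299.9, 300.1, 300, 300)) - 3 * sd(c(299.9, 300.1, 300, 300)))
})

test_that("simulated LOD under packaged defaults sits below a micromolar", {
  p <- pulse_config()
  lods <- vapply(1:6, function(k) {
    dat <- purrr::map_dfr(seq_along(ladder), function(i) {
      tibble::tibble(
        concentration_M = ladder[i],
        t1_us = vapply(1:4, function(r)
          fitted_t1(t1_for_cu(ladder[i]), seed = k * 1000 + i * 10 + r),
          numeric(1)))
    })
    calk <- tryCatch(build_t1_calibration(dat), warning = function(w) NULL)
    if (is.null(calk) || !calk$invertible) return(NA_real_)
    estimate_lod(calk, dat$t1_us[dat$concentration_M == 0])
  }, numeric(1))
  med <- median(lods, na.rm = TRUE)
  expect_gte(med, 1e-9)
  expect_lte(med, 1e-6)
})

test_that("fluorescence calibration is an exact least-squares line", {
  conc <- c(0.2, 0.4, 0.6, 0.8, 1.0) * 1e-6
  dat <- tibble::tibble(concentration_M = conc, intensity = 1e9 * conc)
  cal <- fit_fluorescence_calibration(dat)
  expect_equal(cal$slope, 1e9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)
  # scale equivariance
  cal2 <- fit_fluorescence_calibration(
    dplyr::mutate(dat, intensity = 2 * intensity))
  expect_equal(cal2$slope, 2 * cal$slope)
  expect_error(fit_fluorescence_calibration(dat[1, ]), "at least 2")
})

test_that("hydroxyl quantification inverts the calibration slope", {
  conc <- c(0.2, 0.4, 0.6, 0.8, 1.0) * 1e-6
  cal <- fit_fluorescence_calibration(
    tibble::tibble(concentration_M = conc, intensity = 1e9 * conc))
  expect_equal(quantify_oh(cal, 0.9e-6 * 1e9), 0.9)
  expect_equal(quantify_oh(cal, cal$intercept + 1e9 * 0.2e-6), 0.2)
  expect_error(quantify_oh(cal, 2 * max(cal$intensity_range)), "outside")
  # affine equivariance under common rescaling
  s <- 3.7
  cal_s <- fit_fluorescence_calibration(
    tibble::tibble(concentration_M = conc, intensity = s * 1e9 * conc))
  expect_equal(quantify_oh(cal_s, s * 0.9e-6 * 1e9),
               quantify_oh(cal, 0.9e-6 * 1e9))
})

test_that("calibrations survive a JSON round trip", {
  cal <- noiseless_t1_calib()
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$levels, cal$levels)
  expect_equal(invert_t1(back, predict_t1(back, 3e-5))$concentration_M, 3e-5,
               tolerance = 1e-6)

  fl <- fit_fluorescence_calibration(tibble::tibble(
    concentration_M = c(1e-7, 5e-7, 1e-6), intensity = c(100, 500, 1000)))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_calibration(fl, f2)
  expect_equal(read_calibration(f2)$slope, fl$slope)
})
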