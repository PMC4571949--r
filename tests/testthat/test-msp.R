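test_that("difference spectra have the signs forced by the two templates", {
  ds0 <- build_difference(480, 480, 1, 1)
  expect_true(all(ds0$value == 0))
  ds <- build_difference(480, 560, 1, 1)
  at <- function(wl) ds$value[ds$wavelength == wl]
  expect_gt(at(560), 0)
  expect_lt(at(480), 0)
  expect_error(build_difference(480, 560, -1, 1), "non-negative")
})

test_that("difference-spectrum extrema match the frozen dense-scan fixture", {
  # regression fixture: 1-nm scan of DS(480, 560, 1, 1) over 300-700 nm
  ds <- build_difference(480, 560, 1, 1, grid = 300:700)
  expect_equal(ds$wavelength[which.min(ds$value)], 469)
  expect_equal(min(ds$value), -0.7135356, tolerance = 1e-6)
  expect_equal(ds$wavelength[which.max(ds$value)], 568)
  expect_equal(max(ds$value), 0.9394654, tolerance = 1e-6)
})

test_that("decomposition inverts noiseless difference spectra exactly", {
  for (lmM in c(530, 545, 560)) {
    ds <- build_difference(480, lmM, 1, 1)
    fit <- fit_difference(ds, lambda_max_R_fixed = 480)
    expect_equal(fit$lambda_max_M, lmM, tolerance = 0.03 / lmM)
    expect_equal(fit$amplitude_M, 1, tolerance = 1e-3)
    expect_equal(fit$amplitude_R, 1, tolerance = 1e-3)
    expect_false(fit$clamped)
    expect_gt(fit$correlation, 0.999999)
  }
})

test_that("unequal amplitudes are recovered at randomized peak positions", {
  set.seed(31)
  for (i in 1:5) {
    lmR <- runif(1, 470, 495)
    lmM <- runif(1, 540, 575)
    ds <- build_difference(lmR, lmM, amplitude_R = 0.8, amplitude_M = 0.6)
    fit <- fit_difference(ds, lambda_max_R_fixed = lmR)
    expect_equal(fit$lambda_max_M, lmM, tolerance = 0.1 / lmM)
    expect_equal(fit$amplitude_M, 0.6, tolerance = 0.01)
    expect_equal(fit$amplitude_R, 0.8, tolerance = 0.01)
  }
})

test_that("scaling the data scales both amplitudes and nothing else", {
  ds <- simulate_difference(480, 555, 0.9, 0.7, noise_sigma = 0.01,
                            seed = 9)
  f1 <- fit_difference(ds, 480)
  c_ <- 2.5
  ds2 <- spectrum(ds$wavelength, c_ * ds$value, kind = "difference")
  f2 <- fit_difference(ds2, 480)
  expect_equal(f2$lambda_max_M, f1$lambda_max_M, tolerance = 1e-6)
  expect_equal(f2$amplitude_M, c_ * f1$amplitude_M, tolerance = 1e-6)
  expect_equal(f2$amplitude_R, c_ * f1$amplitude_R, tolerance = 1e-6)
  expect_equal(f2$correlation, f1$correlation, tolerance = 1e-10)
})

test_that("degenerate and infeasible decompositions are handled", {
  g <- default_grid()
  zero <- spectrum(g, rep(0, length(g)), kind = "difference")
  expect_error(fit_difference(zero, 480), "degenerate")
  # a difference spectrum with a *positive* R-form lobe cannot be written
  # as aM*T_M - aR*T_R with aR >= 0: the offending amplitude is clamped
  pos <- spectrum(g, alpha_band(g, template_params(560)) +
                      0.3 * alpha_band(g, template_params(480)),
                  kind = "difference")
  fit <- fit_difference(pos, 480)
  expect_true(fit$clamped)
  expect_equal(fit$amplitude_R, 0)
  expect_gte(fit$amplitude_M, 0)
})

test_that("a drifting baseline is absorbed by the optional offset term", {
  ds <- build_difference(480, 555, 0.9, 0.8)
  drifted <- spectrum(ds$wavelength, ds$value + 0.05, kind = "difference")
  fit <- fit_difference(drifted, 480, offset = TRUE)
  expect_equal(fit$lambda_max_M, 555, tolerance = 0.05 / 555)
  expect_equal(fit$baseline, 0.05, tolerance = 1e-3)
  expect_equal(fit$amplitude_M, 0.8, tolerance = 1e-2)
  # without the offset the fit still runs but reports the drift as error
  plain <- fit_difference(drifted, 480)
  expect_equal(plain$baseline, 0)
})

test_that("transmission converts to absorbance by -log10", {
  tr <- spectrum(c(500, 510), c(0.1, 1), kind = "absorbance")
  a <- absorbance_from_transmission(tr)
  expect_equal(a$value, c(1, 0))
  bad <- spectrum(c(500, 510), c(0, 0.5), kind = "difference")
  expect_error(absorbance_from_transmission(bad), "transmissions")
})
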