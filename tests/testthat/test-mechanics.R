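test_that("effective acceleration follows the density ratio", {
  expect_equal(effective_acceleration(9.8, densities(1, 1)), 0)
  expect_equal(effective_acceleration(1, densities(1, 1e12)), 1,
               tolerance = 1e-9)
  expect_equal(effective_acceleration(1, densities(1.0, 2.9)), 1 - 1 / 2.9)
  expect_error(densities(1, 0), "> 0")
})

test_that("frequency response matches the complex oscillator solution", {
  p <- mechanics_params(gamma = 0.3, k = 2, force = 5)
  # static limit: purely real F/k
  x0 <- frequency_response(p, 0)
  expect_equal(Re(x0), 5 / 2)
  expect_equal(Im(x0), 0)
  # zero drag: flat at F/k for every f
  pg0 <- mechanics_params(gamma = 0, k = 2, force = 5)
  expect_equal(Mod(frequency_response(pg0, c(0, 1, 10, 1e4))),
               rep(2.5, 4))
  # half-power point: |1/(1+i)| = 1/sqrt(2), phase -45 deg
  ph <- mechanics_params(gamma = 1 / (2 * pi), k = 1, force = 1)
  x1 <- frequency_response(ph, 1)
  expect_equal(Mod(x1), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(Arg(x1) * 180 / pi, -45, tolerance = 1e-9)
  # linearity in F
  expect_equal(frequency_response(mechanics_params(0.3, 2, 10), 7),
               2 * frequency_response(p, 7))
})

test_that("amplitude curve has plateau, monotone decay and 1/f asymptote", {
  p <- mechanics_params(gamma = 0.05, k = 2, force = 1)
  f <- 10^seq(-1, 6, length.out = 60)
  curve <- predict_amplitude_curve(p, f)
  expect_true(all(diff(curve$amplitude_nm) <= 0))
  # halving k doubles the low-frequency plateau
  p2 <- mechanics_params(gamma = 0.05, k = 1, force = 1)
  expect_equal(predict_amplitude_curve(p2, 1e-3)$amplitude_nm,
               2 * predict_amplitude_curve(p, 1e-3)$amplitude_nm,
               tolerance = 1e-6)
  # log-log slope -> -1 well past the corner frequency
  fhi <- 1e4 * p$k / (2 * pi * p$gamma)
  a <- predict_amplitude_curve(p, c(fhi, 2 * fhi))$amplitude_nm
  slope <- diff(log(a)) / log(2)
  expect_equal(slope, -1, tolerance = 0.01)
  # phase falls monotonically from 0 towards -90 degrees
  phase <- Arg(frequency_response(p, f)) * 180 / pi
  expect_true(all(diff(phase) < 0))
  expect_gt(phase[1], -1)
  expect_lt(phase[length(f)], -89.9)
  expect_error(predict_amplitude_curve(p, numeric(0)), "empty")
})

test_that("noiseless fits round-trip the identifiable ratios", {
  p <- mechanics_params(gamma = 0.05, k = 2, force = 1)
  curve <- predict_amplitude_curve(p, 10^seq(0, 3, length.out = 8),
                                   organ = "saccule")
  fit <- fit_mechanics(curve)
  expect_equal(unname(fit$ratios["F_over_k"]), 1 / 2, tolerance = 1e-6)
  expect_equal(unname(fit$ratios["F_over_gamma"]), 1 / 0.05,
               tolerance = 1e-6)
  expect_false(fit$gamma_zero)
  expect_lt(fit$residual_norm, 1e-6)
  # absolute parameters when the force is fixed
  fitF <- fit_mechanics(curve, force = 1)
  expect_equal(fitF$k, 2, tolerance = 1e-6)
  expect_equal(fitF$gamma, 0.05, tolerance = 1e-6)
  # methods
  expect_named(coef(fit), c("F_over_k", "F_over_gamma"))
  pred <- predict(fit, c(5, 50))
  expect_s3_class(pred, "amplitude_curve")
  expect_equal(pred$amplitude_nm,
               Mod(frequency_response(p, c(5, 50))), tolerance = 1e-5)
  expect_length(residuals(fit), 8)
  expect_output(print(summary(fit)), "corner frequency")
})

test_that("flat curves flag gamma ~ 0 and report the plateau", {
  curve <- amplitude_curve(c(1, 10, 100), rep(7, 3))
  fit <- fit_mechanics(curve)
  expect_true(fit$gamma_zero)
  expect_identical(unname(fit$ratios["F_over_gamma"]), Inf)
  expect_equal(unname(fit$ratios["F_over_k"]), 7, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_mechanics(amplitude_curve(5, 3)), ">= 2 distinct")
  expect_error(fit_mechanics(data.frame(frequency_hz = c(1, 2),
                                        amplitude_nm = c(4, 4))),
               "underdetermined")
  expect_error(mechanics_params(-1, 1), ">= 0")
  expect_error(mechanics_params(1, 0), "> 0")
})

test_that("simulate() draws noisy curves around the fit", {
  p <- mechanics_params(gamma = 0.05, k = 2, force = 1)
  fit <- fit_mechanics(predict_amplitude_curve(p, 10^seq(0, 3, length.out = 8)))
  sims <- simulate(fit, nsim = 3, seed = 11, noise_sd = 0.1)
  expect_length(sims, 3)
  expect_false(identical(sims[[1]], sims[[2]]))
  # reproducible
  sims2 <- simulate(fit, nsim = 3, seed = 11, noise_sd = 0.1)
  expect_identical(sims, sims2)
})

test_that("amplitude curve CSV round-trips", {
  curve <- predict_amplitude_curve(mechanics_params(0.01, 1), c(1, 10, 100),
                                   organ = "utricle")
  path <- withr::local_tempfile(fileext = ".csv")
  write_amplitude_curve(curve, path)
  curve2 <- read_amplitude_curve(path)
  expect_equal(curve2$amplitude_nm, curve$amplitude_nm)
  expect_equal(attr(curve2, "organ"), "utricle")
})
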