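test_that("attenuation correction inverts attenuation exactly", {
  fx <- iq_fixture()
  sino <- fx$trues_shape
  att <- fx$attenuation
  expect_identical(attenuation_correct(sino, array(1, dim(sino))), sino)
  one <- array(75, c(1, 1, 1))
  expect_equal(attenuation_correct(one, array(0.75, c(1, 1, 1)))[1], 100)
  # forward-attenuate then correct: algebraic round trip
  expect_equal(attenuation_correct(sino * att, att), sino, tolerance = 1e-9)
  expect_error(attenuation_correct(one, array(0, c(1, 1, 1))), "0, 1")
  expect_error(attenuation_correct(sino, att[, , 1, drop = FALSE]), "shape")
})

test_that("scatter estimation: truth mode is exact, tail fit recovers the mass", {
  fx <- iq_fixture()
  w <- energy_window(350, 750)
  sim <- simulate_iq_sinograms(fx$phantom, w, fx$config, pgf = 0.31,
                               trues_shape = fx$trues_shape,
                               attenuation = fx$attenuation)
  expect_identical(estimate_scatter(sinogram_prompts(sim$ss), "truth", ss = sim$ss),
                   sim$ss$scatter)

  # tail fit needs out-of-object bins: wide-FOV configuration
  wide <- acquisition_config(n_radial = 96)
  ph <- fx$phantom
  sim_w <- simulate_iq_sinograms(ph, w, wide, pgf = 0)
  est <- estimate_scatter(sim_w$ss$true_ + sim_w$ss$scatter, "tail_fit",
                          config = wide, object_radius_mm = 17)
  expect_lt(abs(sum(est) - sum(sim_w$ss$scatter)) / sum(sim_w$ss$scatter), 0.15)

  expect_true(all(estimate_scatter(array(0, c(4, 96, 1)), "tail_fit",
                                   config = wide, object_radius_mm = 17) == 0))
  # a support radius covering the whole FOV leaves no tail bins
  expect_error(estimate_scatter(sinogram_prompts(sim$ss), "tail_fit",
                                config = fx$config, object_radius_mm = 25),
               "outside the object support")
})

test_that("prompt-gamma correction: arithmetic, linearity, preserved negatives", {
  e <- array(100, c(2, 3, 1)); s <- array(50, c(2, 3, 1))
  expect_identical(prompt_gamma_correct(e, s, 0), e)
  expect_equal(prompt_gamma_correct(e, s, 0.31)[1], 84.5)
  expect_error(prompt_gamma_correct(e, s[, 1:2, , drop = FALSE], 0.1), "shape")

  # linearity: correcting a sum equals the sum of corrections (same split)
  e2 <- array(runif(6, 50, 150), c(2, 3, 1))
  lhs <- prompt_gamma_correct(e + e2, s, 0.31)
  rhs <- prompt_gamma_correct(e, s, 0.31) + prompt_gamma_correct(e2, array(0, dim(s)), 0.31)
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # negatives are preserved, never clipped
  low <- array(1, c(1, 1, 1))
  res <- prompt_gamma_correct(low, array(100, c(1, 1, 1)), 0.31)
  expect_equal(res[1], 1 - 31)
})

test_that("dead-time correction inverts the non-paralyzable model", {
  expect_equal(deadtime_correct(123, 0), 123)
  expect_equal(deadtime_correct(9.09e4, 1e-6), 9.09e4 / (1 - 9.09e4 * 1e-6))
  r <- 8e4; tau <- 2e-6
  observed <- r / (1 + r * tau)
  expect_equal(deadtime_correct(observed, tau), r, tolerance = 1e-9)
  expect_error(deadtime_correct(1e6, 1e-6), "< 1")
})

test_that("decay correction doubles counts after one half-life", {
  expect_equal(decay_correct(500, 0, isotope("I124")), 500)
  expect_equal(decay_correct(500, 4.18 * 86400, isotope("I124")), 1000)
  expect_equal(decay_correct(500, 109.74 * 60, isotope("F18")), 1000)
  expect_error(decay_correct(500, -1, isotope("F18")), "elapsed")
})

test_that("normalization divides by the efficiency pattern and round-trips", {
  sino <- array(runif(24, 10, 20), c(2, 3, 4))
  expect_identical(normalize_sinogram(sino, 1), sino)
  eff <- array(runif(24, 0.5, 2), c(2, 3, 4))
  expect_equal(normalize_sinogram(sino * eff, eff), sino, tolerance = 1e-9)
  expect_error(normalize_sinogram(sino, 0), "positive")
})

test_that("correction ledger records order and rejects duplicates", {
  led <- correction_ledger()
  led <- record_correction(led, "normalization")
  led <- record_correction(led, "attenuation", list(source = "analytic"))
  expect_equal(format(led), "normalization -> attenuation")
  expect_error(record_correction(led, "attenuation"), "already applied")
})

test_that("the standard chain applies corrections in the documented order", {
  fx <- iq_fixture()
  sim <- simulate_iq_sinograms(fx$phantom, energy_window(350, 750), fx$config,
                               pgf = 0.31, trues_shape = fx$trues_shape,
                               attenuation = fx$attenuation)
  ss <- apply_poisson(sim$ss, seed = 3)
  res <- correct_emission(ss, fx$attenuation, pgf = 0.31,
                          correction_set = "AC+SC+PGF")
  names_in_order <- vapply(res$ledger, function(e) e$name, character(1))
  expect_equal(names_in_order,
               c("normalization", "dead_time", "randoms_subtraction",
                 "attenuation", "scatter", "prompt_gamma", "decay"))
  # the noiseless expectation recovers the attenuation-corrected trues minus
  # the PGF-scaled scatter leakage
  ss0 <- sim$ss
  ss0$prompts <- sinogram_prompts(ss0)
  res0 <- correct_emission(ss0, fx$attenuation, pgf = 0.31,
                           correction_set = "AC+SC+PGF")
  manual <- (ss0$true_ + ss0$prompt_gamma - 0.31 * ss0$scatter) / fx$attenuation
  expect_equal(res0$sinogram, manual, tolerance = 1e-9)
})
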