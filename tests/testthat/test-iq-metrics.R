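test_that("nonuniformity: constant image, hand-computed SD, scale invariance", {
  grid <- voxel_grid(c(40, 40, 8), c(0.776, 0.776, 2.5))
  mask <- voxelize_region(cylinder_region(c(0, 0, 0), 10, 10), grid)

  img <- array(100, grid$shape)
  expect_equal(nonuniformity(img, mask), 0)

  # three-voxel VOI {90, 100, 110}: sample SD is 10, so NU = 10%
  tiny_mask <- array(FALSE, grid$shape); tiny_mask[1:3, 1, 1] <- TRUE
  img[1:3, 1, 1] <- c(90, 100, 110)
  expect_equal(nonuniformity(img, tiny_mask), 10)

  noisy <- array(stats::rnorm(prod(grid$shape), 100, 7), grid$shape)
  expect_equal(nonuniformity(3.7 * noisy, mask), nonuniformity(noisy, mask),
               tolerance = 1e-12)
  expect_error(nonuniformity(img * 0, mask), "positive")
  expect_error(nonuniformity(img, array(FALSE, grid$shape)), "empty")
})

test_that("spillover ratio: zero, published row arithmetic, sign preserved", {
  grid <- voxel_grid(c(20, 20, 4), c(1, 1, 2))
  mask <- voxelize_region(cylinder_region(c(0, 0, 0), 4, 6), grid)
  img <- array(0, grid$shape)
  expect_equal(spillover_ratio(img, mask, 100), 0)
  img[mask] <- -0.0554 * 250
  expect_equal(spillover_ratio(img, mask, 250), -5.54, tolerance = 1e-12)
  expect_error(spillover_ratio(img, mask, 0), "positive")
  expect_error(spillover_ratio(img, array(FALSE, grid$shape), 100), "empty")
})

test_that("recovery coefficients implement the quadrature %SD and noise-floor rule", {
  spec <- iq_phantom_spec()
  grid <- voxel_grid(c(48, 48, 10), c(0.776, 0.776, 2),
                     origin = c(-47 / 2 * 0.776, -47 / 2 * 0.776, -24))
  # constant rod section at the uniform level: RC = 1, zero profile spread
  img <- array(100, grid$shape)
  rc <- recovery_coefficients(img, grid, spec, uniform_mean = 100,
                              uniform_sd = 5)
  expect_equal(rc$rc, rep(1, 5))
  # profile SD is 0, so the quadrature reduces to the uniform CV alone
  expect_equal(rc$pct_sd, rep(100 * 5 / 100, 5))

  # axial modulation with CV 0.10 against uniform CV 0.05:
  # %SD = 100 * sqrt(0.1^2 + 0.05^2) = 11.18
  zmod <- 100 * (1 + 0.1 * sqrt(2) * cos(2 * pi * seq_len(10) / 10))
  img2 <- array(rep(zmod, each = 48 * 48), grid$shape)
  rc2 <- recovery_coefficients(img2, grid, spec, uniform_mean = mean(zmod),
                               uniform_sd = 0.05 * mean(zmod))
  z <- axis_coords(grid, 3)
  profile <- zmod[abs(z + 15) <= 5]  # the slices the estimator averages
  profile_cv <- stats::sd(profile) / mean(profile)
  expect_equal(rc2$pct_sd,
               rep(100 * sqrt(profile_cv^2 + 0.05^2), 5), tolerance = 1e-9)
  expect_equal(round(100 * sqrt(0.10^2 + 0.05^2), 2), 11.18)

  # rods below the noise floor are reported not discernible
  rc3 <- recovery_coefficients(img, grid, spec, uniform_mean = 100,
                               uniform_sd = 40)  # floor = 3*40 = 120 > 100
  expect_true(all(!rc3$discernible))
  expect_true(all(is.na(rc3$rc)))
})

test_that("partial volume: small rods recover less than large rods", {
  fx <- iq_fixture()
  w <- energy_window(350, 750)
  sim <- simulate_iq_sinograms(fx$phantom, w, fx$config, pgf = 0,
                               trues_shape = fx$trues_shape,
                               attenuation = fx$attenuation)
  ss <- apply_poisson(sim$ss, seed = 9)
  rods_slices <- grid_slices(fx$grid, -15, 5)
  uni_slices <- grid_slices(fx$grid, 2.5, 5)
  imgs_r <- reconstruct_correction_sets(ss, fx$attenuation, 0, fx$grid,
                                        fx$config, "AC", slices = rods_slices)
  imgs_u <- reconstruct_correction_sets(ss, fx$attenuation, 0, fx$grid,
                                        fx$config, "AC", slices = uni_slices)
  umask <- voxelize_region(iq_vois(fx$spec)$uniform, attr(imgs_u, "subgrid"))
  uvals <- imgs_u$AC[umask]
  rc <- recovery_coefficients(imgs_r$AC, attr(imgs_r, "subgrid"), fx$spec,
                              mean(uvals), stats::sd(uvals))
  expect_false(rc$discernible[rc$rod_mm == 1])
  expect_gt(rc$rc[rc$rod_mm == 5], rc$rc[rc$rod_mm == 2])
})

test_that("weighted SOR reproduces the published column and its properties", {
  sor <- published_sor_table()
  w <- weighted_sor(sor$sor_air_pct, sor$sor_water_pct)
  expect_true(all(abs(w - sor$wsor) <= 0.01))
  expect_equal(round(w[sor$uld_keV == 750], 2), 0.95)
  expect_equal(round(w[sor$uld_keV == 600 & sor$lld_keV == 350], 2), 1.43)
  expect_equal(round(w[sor$uld_keV == 590], 2), 1.67)

  expect_equal(weighted_sor(0, 0), 0)
  # monotone in each |SOR| separately
  expect_gt(weighted_sor(-6, 1), weighted_sor(-5, 1))
  expect_gt(weighted_sor(-5, 2), weighted_sor(-5, 1))
  expect_error(weighted_sor(1, 1, f_air = 0.5, f_water = 0.4), "sum to 1")
  expect_error(weighted_sor(1, 1, f_air = -0.1, f_water = 1.1), "non-negative")
})

test_that("optimal window selection: published table, singleton, tie break", {
  sor <- published_sor_table()
  sor$wsor <- weighted_sor(sor$sor_air_pct, sor$sor_water_pct)
  best <- select_optimal_window(sor)
  expect_equal(window_label(best), "350~750")

  single <- sor[3, ]
  expect_equal(window_label(select_optimal_window(single)),
               window_label(energy_window(single$lld_keV, single$uld_keV)))

  tie <- data.frame(lld_keV = c(350, 350), uld_keV = c(600, 700),
                    wsor = c(1, 1))
  expect_message(tw <- select_optimal_window(tie), "tie")
  expect_equal(tw$uld, 700)
  expect_error(select_optimal_window(sor[0, ]), "no reports")
})
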