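test_that("forward projector: zero volume, point-source symmetry, disk chord profile", {
  grid <- voxel_grid(c(64, 64, 1), c(0.776, 0.776, 2.5))
  cfg <- acquisition_config()

  expect_warning(z <- radon_transform(array(0, grid$shape), grid, cfg), "empty")
  expect_true(all(z == 0))

  # centred point source: every angle peaks at the central radial bins
  pt <- array(0, grid$shape)
  pt[32, 32, 1] <- 1  # voxel centres straddle the axis; this one is ~0.39 mm off
  sino <- radon_transform(pt, grid, cfg)
  central <- cfg$n_radial / 2 + (-1:2)
  for (a in seq(1, cfg$n_angles, by = 8)) {
    expect_true(which.max(sino[a, , 1]) %in% central)
  }

  # uniform disk projects to the analytic chord-length profile (< 2% RMS);
  # the disk is anti-aliased (4x4 subvoxel coverage) so the comparison
  # measures projector error, not voxelization error
  xs <- axis_coords(grid, 1)
  cover <- function(xc, yc) {
    off <- (1:4 - 2.5) / 4 * grid$voxel_size[1]
    mean(outer(xc + off, yc + off, function(a, b) a^2 + b^2) <= 144)
  }
  disk <- array(0, grid$shape)
  disk[, , 1] <- outer(xs, xs, Vectorize(cover))
  sino <- radon_transform(disk, grid, cfg)
  s <- radial_coords(cfg)
  # analytic chord length averaged over each finite radial bin
  expected <- vapply(s, function(si) {
    u <- seq(si - cfg$radial_bin_size / 2, si + cfg$radial_bin_size / 2,
             length.out = 101)
    mean(disk_chord(u, 12))
  }, numeric(1))
  for (a in c(1, 25, 60)) {
    rms <- sqrt(mean((sino[a, , 1] - expected)^2)) / max(expected)
    expect_lt(rms, 0.02)
  }
})

test_that("attenuation factors: air, analytic water cylinder, edge monotonicity", {
  grid <- voxel_grid(c(64, 64, 2), c(0.776, 0.776, 2.5))
  cfg <- acquisition_config()

  air <- array(0L, grid$shape)
  expect_true(all(attenuation_factors(air, grid, cfg) == 1))

  water <- array(0L, grid$shape)
  water[voxelize_region(cylinder_region(c(0, 0, 0), 15, 10), grid)] <- 1L
  att <- attenuation_factors(water, grid, cfg)
  expect_true(all(att > 0 & att <= 1))
  # central line crosses 30 mm of water: exp(-0.096/cm * 3 cm) ~ 0.750
  s <- radial_coords(cfg)
  centre <- which.min(abs(s))
  expect_equal(att[1, centre, 1], exp(-0.0096 * 30), tolerance = 0.01)
  # factors rise towards lines missing the phantom
  outer_half <- att[1, centre:cfg$n_radial, 1]
  expect_true(all(diff(outer_half) > -1e-9))
  expect_equal(att[1, cfg$n_radial, 1], 1, tolerance = 1e-6)
})

test_that("scatter component: mass ratio, smoothness, zero fraction", {
  fx <- iq_fixture()
  trues <- fx$trues_shape[, , 10, drop = FALSE]

  expect_true(all(scatter_component(trues, 0) == 0))

  sc <- scatter_component(trues, 0.25, sigma_bins = 12)
  expect_equal(sum(sc) / sum(trues), 0.25 / 0.75, tolerance = 1e-6)
  # strictly smoother than the emission it derives from
  grad <- function(x) max(abs(diff(x[1, , 1])))
  expect_lt(grad(sc), grad(trues))

  expect_error(scatter_component(trues, 1), "scatter_fraction")
})

test_that("prompt-gamma component: mass bookkeeping and flat shape", {
  fx <- iq_fixture()
  trues <- fx$trues_shape[, , 8:10]
  sc <- scatter_component(trues, 0.1)

  expect_true(all(prompt_gamma_component(trues, sc, 0) == 0))

  pg <- prompt_gamma_component(trues, sc, 0.31)
  prompts <- trues + sc + pg
  expect_equal(sum(pg) / sum(prompts), 0.31, tolerance = 1e-6)
  expect_lt(stats::sd(pg) / mean(pg), 1e-6)  # flat before noise

  pg_obj <- prompt_gamma_component(trues, sc, 0.31, shape = "object")
  expect_equal(sum(pg_obj), sum(pg), tolerance = 1e-9)

  expect_error(prompt_gamma_component(trues, sc, 1), "pgf")
})

test_that("randoms component follows the activity-squared law", {
  cfg <- acquisition_config(randoms_coefficient = 40)
  dims <- c(8, 8, 2)
  expect_true(all(randoms_component(0, cfg, dims) == 0))
  r1 <- randoms_component(2, cfg, dims, duration_s = 10)
  r2 <- randoms_component(4, cfg, dims, duration_s = 10)
  expect_equal(sum(r2) / sum(r1), 4, tolerance = 1e-12)
  # 40 cps/MBq^2 at 5 MBq -> 1000 cps in total
  r5 <- randoms_component(5, cfg, dims, duration_s = 1)
  expect_equal(sum(r5), 1000, tolerance = 1e-9)
})

test_that("Poisson sampling: zero expectation, determinism, unbiasedness", {
  zero <- sinogram_set(array(0, c(4, 4, 1)))
  expect_true(all(apply_poisson(zero, seed = 1)$prompts == 0))

  ss <- sinogram_set(array(50, c(10, 10, 10)))
  a <- apply_poisson(ss, seed = 77)
  b <- apply_poisson(ss, seed = 77)
  expect_identical(a$prompts, b$prompts)

  # CLT bound: mean of 1000 bins with expectation 50
  expect_lt(abs(mean(a$prompts) - 50), 3 * sqrt(50 / 1000))
})

test_that("component additivity and duration scaling are exact", {
  fx <- iq_fixture()
  w <- energy_window(350, 750)
  sim1 <- simulate_iq_sinograms(fx$phantom, w, fx$config, pgf = 0.31,
                                duration_s = 1000, count_scale = 1e-3,
                                trues_shape = fx$trues_shape,
                                attenuation = fx$attenuation)
  ss <- sim1$ss
  expect_identical(sinogram_prompts(ss),
                   ss$true_ + ss$scatter + ss$random + ss$prompt_gamma)
  sim2 <- simulate_iq_sinograms(fx$phantom, w, fx$config, pgf = 0.31,
                                duration_s = 2000, count_scale = 1e-3,
                                trues_shape = fx$trues_shape,
                                attenuation = fx$attenuation)
  expect_equal(sinogram_prompts(sim2$ss), 2 * sinogram_prompts(ss),
               tolerance = 1e-12)
})

test_that("sensitivity acquisition recovers the geometric sensitivity and honours the dead-time guard", {
  cfg <- acquisition_config(intrinsic_background_cps = 0)
  f18 <- isotope("F18")
  w <- cfg$reference_window
  # noiseless, pure emitter: counts/duration/activity/branching recovers
  # sensitivity exactly
  acq <- simulate_sensitivity_acquisition(f18, w, 0, 673e3, 300, cfg)
  s <- absolute_sensitivity(acq$prompt_counts, 0, 300, 673e3, isotope = f18)
  expect_equal(s / 100 / f18$branching_ratio, cfg$sensitivity, tolerance = 1e-6)

  # the protocol activities run below the 1% dead-time loss guard
  cfg2 <- acquisition_config()
  expect_no_warning(simulate_sensitivity_acquisition(isotope("I124"), w, 0.31,
                                                     506e3, 300, cfg2))
  expect_no_warning(simulate_sensitivity_acquisition(f18, w, 0, 673e3, 300, cfg2))
  # a hot source does not
  expect_warning(simulate_sensitivity_acquisition(f18, w, 0, 5e7, 300, cfg2),
                 "dead time")
})

test_that("count-rate model: linear limit, dead-time asymptote, window PGF", {
  w <- energy_window(350, 750)
  lin_cfg <- acquisition_config(deadtime_tau = 0, randoms_coefficient = 0)
  rates <- simulate_countrates(1:10, w, lin_cfg, isotope("F18"))
  expect_equal(rates$trues / rates$trues[1], 1:10, tolerance = 1e-12)
  expect_true(all(rates$prompt_gamma == 0))  # pure emitter

  # total observed rate approaches 1/tau for large activity
  cfg <- acquisition_config()
  hot <- simulate_countrates(c(1e4, 1e5), w, cfg)
  total <- rowSums(hot[, c("trues", "scatter", "randoms", "prompt_gamma")])
  expect_equal(total[2], 1 / cfg$deadtime_tau, tolerance = 0.05)

  # 400~590: prompt-gamma rate is 2% of the coincidence rate
  r <- simulate_countrates(5, energy_window(400, 590), cfg)
  coin <- r$trues + r$scatter + r$prompt_gamma
  expect_equal(r$prompt_gamma / coin, 0.02, tolerance = 1e-9)
})

test_that("sinograms round-trip through the raw + JSON sidecar format", {
  cfg <- acquisition_config(n_radial = 8, n_angles = 6)
  sino <- array(rpois(6 * 8 * 2, 20), c(6, 8, 2))
  path <- tempfile()
  write_sinogram(sino, path, cfg, window = energy_window(350, 750),
                 extra = list(ledger = "normalization -> attenuation"))
  back <- read_sinogram(path)
  expect_equal(back$sinogram, sino, ignore_attr = TRUE)
  expect_equal(back$meta$window, "350~750")
  expect_equal(back$meta$ledger, "normalization -> attenuation")
})
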