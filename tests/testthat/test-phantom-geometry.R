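test_that("IQ phantom voxelization matches analytic volumes and material rules", {
  grid <- voxel_grid(c(64, 64, 52), c(0.776, 0.776, 1))
  spec <- iq_phantom_spec(activity_concentration = 1e5)
  ph <- build_iq_phantom(spec, grid)

  # active uniform-region volume vs analytic cylinder volume
  umask <- voxelize_region(spec$uniform_region, grid)
  vox_vol <- sum(umask) * prod(grid$voxel_size)
  expect_lt(abs(vox_vol - cylinder_volume(spec$uniform_region)) /
              cylinder_volume(spec$uniform_region), 0.03)
  expect_true(all(ph$activity[umask] == spec$activity_concentration))

  # cold chambers: nonradioactive, correct materials
  air <- voxelize_region(spec$cold_air, grid)
  water <- voxelize_region(spec$cold_water, grid)
  expect_true(all(ph$activity[air] == 0))
  expect_true(all(ph$activity[water] == 0))
  expect_true(all(ph$material[air] == 0L))    # air
  expect_true(all(ph$material[water] == 1L))  # water

  # activity is non-negative and zero wherever material is air
  expect_true(all(ph$activity >= 0))
  expect_true(all(ph$activity[ph$material == 0L] == 0))

  # zero concentration -> identically zero activity
  ph0 <- build_iq_phantom(iq_phantom_spec(activity_concentration = 0), grid)
  expect_true(all(ph0$activity == 0))

  # grid not covering the phantom is an explicit error
  expect_error(build_iq_phantom(spec, voxel_grid(c(16, 16, 16), 0.776)),
               "does not cover")
})

test_that("rod masks are pairwise disjoint and inside the body", {
  grid <- voxel_grid(c(96, 96, 30), c(0.4, 0.4, 2))
  spec <- iq_phantom_spec()
  masks <- lapply(spec$rods, voxelize_region, grid = grid)
  body <- voxelize_region(spec$body, grid)
  for (i in seq_along(masks)) {
    expect_true(all(body[masks[[i]]]))
    for (j in seq_along(masks)) {
      if (j > i) expect_false(any(masks[[i]] & masks[[j]]))
    }
  }
})

test_that("mouse phantom has the analytic volume, exact activity, centred mass", {
  grid <- voxel_grid(c(120, 120, 80), c(0.25, 0.25, 1))
  mp <- build_mouse_phantom(grid, diameter = 25, length = 70,
                            total_activity_bq = 1e6)
  vol_ml <- sum(mp$activity > 0) * voxel_volume_ml(grid)
  expect_lt(abs(vol_ml - 34.36) / 34.36, 0.03)
  expect_equal(sum(mp$activity) * voxel_volume_ml(grid), 1e6, tolerance = 1e-9)
  # centre of mass within one voxel of the grid centre
  idx <- which(mp$activity > 0, arr.ind = TRUE)
  com <- colMeans(idx * 1)
  expect_true(all(abs(com - (dim(mp$activity) + 1) / 2) <= 1))
})

test_that("voxel-centre membership: degenerate and analytic cases", {
  grid <- voxel_grid(c(20, 20, 4), c(1, 1, 5))
  # cylinder smaller than half a voxel, off-centre: possibly empty, no error
  tiny <- cylinder_region(c(0.4, 0.3, 0), radius = 0.2, length = 1)
  expect_silent(m <- voxelize_region(tiny, grid))
  # large cylinder: count within a one-voxel surface shell of the analytic value
  big <- cylinder_region(c(0, 0, 0), radius = 8, length = 20)
  m <- voxelize_region(big, grid)
  analytic <- cylinder_volume(big) / prod(grid$voxel_size)
  shell <- 2 * pi * 8 * 20 / prod(grid$voxel_size)  # one-voxel lateral shell
  expect_lt(abs(sum(m) - analytic), shell)
  # disjoint regions give disjoint masks
  a <- voxelize_region(cylinder_region(c(-5, 0, 0), 2, 10), grid)
  b <- voxelize_region(cylinder_region(c(5, 0, 0), 2, 10), grid)
  expect_false(any(a & b))
})

test_that("voxelized volume converges to the analytic volume with finer voxels", {
  region <- cylinder_region(c(0, 0, 0), radius = 7.3, length = 11)
  err <- sapply(c(1.0, 0.5), function(h) {
    grid <- voxel_grid(c(ceiling(20 / h), ceiling(20 / h), ceiling(16 / h)), h)
    abs(sum(voxelize_region(region, grid)) * h^3 - cylinder_volume(region))
  })
  expect_lt(err[2], err[1] / 2)
})

test_that("volumes and phantom specs round-trip through NIfTI and YAML", {
  grid <- voxel_grid(c(8, 8, 4), c(0.776, 0.776, 2.5))
  vol <- array(rnorm(prod(grid$shape)), grid$shape)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, grid, path)
  back <- read_volume(path)
  expect_equal(back$volume, vol, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$voxel_size[1:3], grid$voxel_size, tolerance = 1e-6,
               ignore_attr = TRUE)

  spath <- tempfile(fileext = ".yaml")
  write_phantom_spec(iq_phantom_spec(activity_concentration = 12345), spath)
  spec2 <- read_phantom_spec(spath)
  expect_equal(spec2$activity_concentration, 12345)
})
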