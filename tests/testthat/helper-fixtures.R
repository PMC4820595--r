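# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# study-default IQ phantom with its (window-independent) projection and
# attenuation factors; memoized because the projection is the slow part
iq_fixture <- function() {
  if (is.null(.fixtures$iq)) {
    grid <- voxel_grid(c(64, 64, 20), c(0.776, 0.776, 2.5))
    cfg <- acquisition_config()
    phantom <- build_iq_phantom(iq_phantom_spec(), grid)
    .fixtures$iq <- list(
      grid = grid, config = cfg, spec = iq_phantom_spec(), phantom = phantom,
      trues_shape = radon_transform(phantom$activity, grid, cfg),
      attenuation = attenuation_factors(phantom$material, grid, cfg)
    )
  }
  .fixtures$iq
}

# analytic Radon transform of a uniform disk: chord length profile
disk_chord <- function(s, radius, value = 1) {
  2 * value * sqrt(pmax(radius^2 - s^2, 0))
}

# slices covering a z-range of the study grid
grid_slices <- function(grid, center_z, half_len) {
  which(abs(axis_coords(grid, 3) - center_z) <= half_len)
}
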