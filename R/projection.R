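# Forward projection (discrete Radon transform) and analytic attenuation
# factors. The simulator works on direct 2D planes: each axial slice is
# projected independently over angles uniformly spaced on [0, 180).

#' Radon transform of a volume, slice by slice
#'
#' Line integrals are evaluated by sampling each line at steps of one in-plane
#' voxel with bilinear interpolation (zero outside the grid), so the output is
#' in units of (input value) x mm.
#'
#' @param volume numeric array (nx, ny, nz) or matrix (nx, ny)
#' @param grid the `voxel_grid` the volume lives on
#' @param config an [acquisition_config()]: number of angles, radial bins and
#'   radial bin size
#' @return array (n_angles, n_radial, n_slices)
#' @export
radon_transform <- function(volume, grid, config) {
  if (is.matrix(volume)) volume <- array(volume, c(dim(volume), 1L))
  d <- dim(volume)
  if (all(volume == 0)) {
    warning("projecting an empty volume: zero sinogram")
    return(array(0, c(config$n_angles, config$n_radial, d[3])))
  }
  dx <- grid$voxel_size[1]
  dy <- grid$voxel_size[2]
  nx <- d[1]; ny <- d[2]
  x0 <- axis_coords(grid, 1)[1]
  y0 <- axis_coords(grid, 2)[1]

  angles <- pi * (seq_len(config$n_angles) - 1) / config$n_angles
  s <- radial_coords(config)
  diag_len <- sqrt((nx * dx)^2 + (ny * dy)^2)
  dt <- dx / 2   # half-voxel steps keep the line-integral error well under 2%
  tt <- seq(-diag_len / 2, diag_len / 2, by = dt)

  out <- array(0, c(config$n_angles, config$n_radial, d[3]))
  for (ai in seq_along(angles)) {
    th <- angles[ai]
    # sample points for all (radial, t) pairs
    xs <- outer(s * cos(th), -tt * sin(th), "+")
    ys <- outer(s * sin(th), tt * cos(th), "+")
    # bilinear interpolation indices/weights (shared across slices)
    fx <- (xs - x0) / dx
    fy <- (ys - y0) / dy
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    inside <- i0 >= 0 & i0 <= nx - 2 & j0 >= 0 & j0 <= ny - 2
    i0c <- pmin(pmax(i0, 0), nx - 2) + 1L
    j0c <- pmin(pmax(j0, 0), ny - 2) + 1L
    idx00 <- cbind(as.vector(i0c), as.vector(j0c))
    idx10 <- cbind(as.vector(i0c) + 1L, as.vector(j0c))
    idx01 <- cbind(as.vector(i0c), as.vector(j0c) + 1L)
    idx11 <- cbind(as.vector(i0c) + 1L, as.vector(j0c) + 1L)
    w00 <- as.vector((1 - wx) * (1 - wy) * inside)
    w10 <- as.vector(wx * (1 - wy) * inside)
    w01 <- as.vector((1 - wx) * wy * inside)
    w11 <- as.vector(wx * wy * inside)
    for (sl in seq_len(d[3])) {
      img <- volume[, , sl]
      vals <- w00 * img[idx00] + w10 * img[idx10] +
              w01 * img[idx01] + w11 * img[idx11]
      dim(vals) <- c(config$n_radial, length(tt))
      out[ai, , sl] <- rowSums(vals) * dt
    }
  }
  out
}

#' Radial bin centre coordinates (mm) of a sinogram
#' @param config an [acquisition_config()]
#' @export
radial_coords <- function(config) {
  (seq_len(config$n_radial) - (config$n_radial + 1) / 2) * config$radial_bin_size
}

#' Coincidence attenuation factors from a material map
#'
#' Replaces a transmission measurement: the survival probability of each
#' coincidence line is exp(-integral of mu along the full line), computed by
#' forward-projecting the 511-keV attenuation map. Lines through air only get
#' a factor of exactly 1.
#'
#' @param material integer label volume (see `MATERIALS`)
#' @param grid its `voxel_grid`
#' @param config an [acquisition_config()]
#' @return array (n_angles, n_radial, n_slices) of factors in (0, 1]
#' @export
attenuation_factors <- function(material, grid, config) {
  mu <- mu_map(material)
  if (all(mu == 0)) {
    return(array(1, c(config$n_angles, config$n_radial, dim(material)[3])))
  }
  exp(-radon_transform(mu, grid, config))
}
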