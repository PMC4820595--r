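# 2D filtered backprojection with a ramp filter, per axial slice.

ramp_filter <- function(n_pad, bin_size, cutoff = 1, apodization = "none") {
  freq <- c(seq(0, n_pad / 2), seq(-n_pad / 2 + 1, -1)) / n_pad  # cycles/bin
  h <- abs(freq) / bin_size                                       # cycles/mm
  nyq <- 0.5 / bin_size
  h[abs(freq) / bin_size > cutoff * nyq] <- 0
  if (apodization == "hann") {
    h <- h * 0.5 * (1 + cos(pi * freq / (0.5 * cutoff)))
  }
  h
}

#' Filtered backprojection reconstruction
#'
#' Reconstructs each axial slice of a sinogram with frequency-domain ramp
#' filtering and linearly interpolated backprojection. The operator is linear;
#' negative sinogram bins produce correspondingly negative image
#' contributions (no clipping), which is required for spillover ratios to be
#' able to go negative after scatter subtraction.
#'
#' @param sinogram array (n_angles, n_radial, n_slices); angles are assumed
#'   uniformly spaced over 180 degrees
#' @param grid output `voxel_grid` (in-plane shape and pixel size; the slice
#'   count must match the sinogram)
#' @param config the [acquisition_config()] the sinogram was generated with
#' @param cutoff frequency cutoff as a fraction of Nyquist (default 1)
#' @param apodization "none" (plain ramp, default) or "hann"
#' @return numeric array (nx, ny, n_slices) in units of (sinogram counts)/mm^2
#' @export
fbp_reconstruct <- function(sinogram, grid, config, cutoff = 1,
                            apodization = c("none", "hann")) {
  apodization <- match.arg(apodization)
  d <- dim(sinogram)
  n_angles <- d[1]; n_radial <- d[2]; n_slices <- d[3]
  if (n_angles < 16) warning("fewer than 16 projection angles: expect streak artifacts")
  bs <- config$radial_bin_size
  angles <- pi * (seq_len(n_angles) - 1) / n_angles
  s <- radial_coords(config)

  n_pad <- 2^ceiling(log2(2 * n_radial))
  h <- ramp_filter(n_pad, bs, cutoff, apodization)

  x <- axis_coords(grid, 1)
  y <- axis_coords(grid, 2)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  xg <- matrix(x, nx, ny)
  yg <- matrix(y, nx, ny, byrow = TRUE)

  out <- array(0, c(nx, ny, n_slices))
  for (sl in seq_len(n_slices)) {
    filtered <- matrix(0, n_angles, n_radial)
    for (a in seq_len(n_angles)) {
      p <- c(sinogram[a, , sl], numeric(n_pad - n_radial))
      q <- Re(stats::fft(stats::fft(p) * h, inverse = TRUE)) / n_pad
      filtered[a, ] <- q[seq_len(n_radial)]
    }
    acc <- matrix(0, nx, ny)
    for (a in seq_len(n_angles)) {
      sp <- xg * cos(angles[a]) + yg * sin(angles[a])
      vals <- stats::approx(s, filtered[a, ], xout = as.vector(sp),
                            yleft = 0, yright = 0)$y
      acc <- acc + matrix(vals, nx, ny)
    }
    out[, , sl] <- acc * pi / n_angles
  }
  out
}

#' Collapse a multi-slice sinogram by single-slice rebinning
#'
#' Averages groups of adjacent slices into one plane. This is a deliberately
#' simple stand-in for rebinning oblique 3D data, which the simulator never
#' produces (it generates direct planes only); it exists so externally
#' supplied multi-slice stacks can be reduced before 2D reconstruction.
#'
#' @param sinogram array (angle, radial, slice)
#' @param span number of adjacent slices averaged per output plane
#' @return array (angle, radial, ceiling(n_slices / span))
#' @export
ssrb_collapse <- function(sinogram, span = 2) {
  if (span < 1) stop("span must be >= 1", call. = FALSE)
  d <- dim(sinogram)
  groups <- split(seq_len(d[3]), ceiling(seq_len(d[3]) / span))
  out <- array(0, c(d[1], d[2], length(groups)))
  for (g in seq_along(groups)) {
    out[, , g] <- apply(sinogram[, , groups[[g]], drop = FALSE], c(1, 2), mean)
  }
  out
}
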