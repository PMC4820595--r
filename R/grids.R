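# Voxel grids and cylindrical regions: all phantom geometry is defined in
# physical millimetres (grid-independent) and voxelized on demand.
#
# Coordinate convention: right-handed, scanner axis = z, units mm, voxel
# indices 1-based in R but voxel (1,1,1) sits at `origin` (mm). The default
# origin centres the grid on the scanner axis.

#' Define a voxel grid
#'
#' @param shape integer vector of length 3: voxels along x, y, z
#' @param voxel_size voxel edge length in mm; scalar (isotropic) or length 3
#' @param origin mm coordinates of the centre of voxel (1,1,1); default
#'   centres the grid on (0, 0, 0)
#' @return an object of class `voxel_grid`
#' @examples
#' g <- voxel_grid(c(64, 64, 20), c(0.776, 0.776, 2.5))
#' @export
voxel_grid <- function(shape, voxel_size, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("'shape' must be three positive integers", call. = FALSE)
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("'voxel_size' must be positive on all axes", call. = FALSE)
  }
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  if (length(origin) != 3L) stop("'origin' must have length 3", call. = FALSE)
  structure(
    list(shape = shape, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' Physical coordinates of voxel centres along one axis
#' @param grid a `voxel_grid`
#' @param axis 1 (x), 2 (y) or 3 (z)
#' @return numeric vector of mm coordinates
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size[axis]
}

#' Voxel volume in millilitres
#' @param grid a `voxel_grid`
#' @return scalar, mL per voxel
#' @export
voxel_volume_ml <- function(grid) {
  prod(grid$voxel_size) / 1000
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3f x %.3f x %.3f mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Define a cylindrical region aligned with the scanner axis
#'
#' @param center mm triple: cylinder centre
#' @param radius mm, > 0
#' @param length mm extent along z, > 0
#' @return an object of class `cylinder_region`
#' @export
cylinder_region <- function(center, radius, length) {
  stopifnot_scalar(radius, "radius")
  stopifnot_scalar(length, "length")
  if (radius <= 0 || length <= 0) {
    stop("cylinder radius and length must be positive", call. = FALSE)
  }
  if (base::length(center) != 3L) stop("'center' must have length 3", call. = FALSE)
  structure(list(center = as.numeric(center), radius = radius, length = length),
            class = "cylinder_region")
}

#' Analytic volume of a cylindrical region, in mm^3
#' @param region a `cylinder_region`
#' @export
cylinder_volume <- function(region) {
  pi * region$radius^2 * region$length
}

#' Voxelize a cylindrical region on a grid
#'
#' A voxel belongs to the region iff its centre lies inside the cylinder
#' (centre-in-region rule; deterministic, no partial-volume weighting).
#' A region smaller than half a voxel may produce an empty mask; that is not
#' an error.
#'
#' @param region a `cylinder_region`
#' @param grid a `voxel_grid`
#' @return logical array with `dim = grid$shape`
#' @export
voxelize_region <- function(region, grid) {
  x <- axis_coords(grid, 1)
  y <- axis_coords(grid, 2)
  z <- axis_coords(grid, 3)
  r2 <- outer((x - region$center[1])^2, (y - region$center[2])^2, "+")
  inplane <- r2 <= region$radius^2
  zin <- abs(z - region$center[3]) <= region$length / 2
  mask <- array(FALSE, grid$shape)
  for (k in which(zin)) mask[, , k] <- inplane
  mask
}
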