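# NEMA NU 4-2008 phantoms as activity (Bq/mL) + material label volumes.
#
# Material labels are integer codes with fixed 511-keV linear attenuation
# coefficients (per mm): air 0, water 0.0096, PMMA 0.0112, aluminum 0.0227.
# The water/PMMA values correspond to the usual 0.096/cm and 0.112/cm.

MATERIALS <- c(air = 0L, water = 1L, pmma = 2L, aluminum = 3L)
MU_PER_MM <- c(air = 0, water = 0.0096, pmma = 0.0112, aluminum = 0.0227)

#' Linear attenuation coefficients (1/mm) for a material label volume
#' @param material integer array of material codes (see `MATERIALS`)
#' @return numeric array of mu values, per mm, same shape
#' @export
mu_map <- function(material) {
  mu <- array(0, dim(material))
  for (m in names(MATERIALS)) {
    mu[material == MATERIALS[[m]]] <- MU_PER_MM[[m]]
  }
  mu
}

#' NEMA NU 4-2008 image-quality phantom specification
#'
#' The phantom is a 30 mm diameter, 50 mm long cylinder in three sections:
#' a fillable uniform region (30 mm diameter, 15 mm long), a cold-chamber
#' section with two 8 mm inner / 10 mm outer diameter chambers (15 mm long;
#' one air-filled, one filled with nonradioactive water), and a rod section
#' (20 mm long) with five fillable rods of 1-5 mm diameter whose centres sit
#' 7 mm from the cylinder axis.
#'
#' @param activity_concentration Bq/mL in the active compartments
#' @param wall_thickness mm of PMMA shell around the 30 mm body (the standard
#'   does not fix it; default 2 mm)
#' @return an object of class `iq_phantom_spec`
#' @export
iq_phantom_spec <- function(activity_concentration = 1e5, wall_thickness = 2) {
  if (activity_concentration < 0) stop("activity must be >= 0", call. = FALSE)
  # z layout: rods [-25, -5], uniform [-5, 10], cold chambers [10, 25]
  rods <- lapply(1:5, function(d) {
    ang <- 2 * pi * (d - 1) / 5
    cylinder_region(center = c(7 * cos(ang), 7 * sin(ang), -15),
                    radius = d / 2, length = 20)
  })
  names(rods) <- paste0("rod_", 1:5, "mm")
  spec <- list(
    body = cylinder_region(c(0, 0, 0), radius = 15, length = 50),
    uniform_region = cylinder_region(c(0, 0, 2.5), radius = 15, length = 15),
    cold_air = cylinder_region(c(-7.5, 0, 17.5), radius = 4, length = 15),
    cold_water = cylinder_region(c(7.5, 0, 17.5), radius = 4, length = 15),
    cold_wall_outer_radius = 5,
    rods = rods,
    rod_section = cylinder_region(c(0, 0, -15), radius = 15, length = 20),
    activity_concentration = activity_concentration,
    wall_thickness = wall_thickness
  )
  # invariant checks: pairwise disjoint rods, chambers inside body
  for (i in 1:4) for (j in (i + 1):5) {
    ci <- rods[[i]]$center; cj <- rods[[j]]$center
    if (sqrt(sum((ci[1:2] - cj[1:2])^2)) < rods[[i]]$radius + rods[[j]]$radius) {
      stop("rod regions overlap", call. = FALSE)
    }
  }
  structure(spec, class = "iq_phantom_spec")
}

check_grid_covers <- function(grid, radius, half_length, what) {
  ext_xy <- (grid$shape[1:2] - 1) / 2 * grid$voxel_size[1:2]
  ext_z <- (grid$shape[3] - 1) / 2 * grid$voxel_size[3] + grid$voxel_size[3] / 2
  if (any(ext_xy < radius) || ext_z < half_length) {
    stop(sprintf("grid does not cover the %s (needs radius %.1f mm, half-length %.1f mm)",
                 what, radius, half_length), call. = FALSE)
  }
}

#' Voxelize the image-quality phantom
#'
#' @param spec an `iq_phantom_spec`
#' @param grid a `voxel_grid` covering the phantom
#' @return list with `activity` (Bq/mL array), `material` (integer label
#'   array), `grid` and `spec`
#' @export
build_iq_phantom <- function(spec = iq_phantom_spec(), grid) {
  outer_r <- spec$body$radius + spec$wall_thickness
  check_grid_covers(grid, outer_r, spec$body$length / 2, "image-quality phantom")

  material <- array(MATERIALS[["air"]], grid$shape)
  activity <- array(0, grid$shape)

  shell <- voxelize_region(cylinder_region(spec$body$center, outer_r,
                                           spec$body$length), grid)
  material[shell] <- MATERIALS[["pmma"]]

  body <- voxelize_region(spec$body, grid)
  material[body] <- MATERIALS[["water"]]
  activity[body] <- spec$activity_concentration

  # rod section: solid PMMA except the fillable rods
  rodsec <- voxelize_region(spec$rod_section, grid)
  material[rodsec] <- MATERIALS[["pmma"]]
  activity[rodsec] <- 0
  for (rod in spec$rods) {
    m <- voxelize_region(rod, grid)
    material[m] <- MATERIALS[["water"]]
    activity[m] <- spec$activity_concentration
  }

  # cold chambers: PMMA wall, nonradioactive interior (one air, one water)
  for (side in c("cold_air", "cold_water")) {
    ch <- spec[[side]]
    wall <- voxelize_region(cylinder_region(ch$center, spec$cold_wall_outer_radius,
                                            ch$length), grid)
    material[wall] <- MATERIALS[["pmma"]]
    activity[wall] <- 0
    inner <- voxelize_region(ch, grid)
    material[inner] <- if (side == "cold_air") MATERIALS[["air"]] else MATERIALS[["water"]]
    activity[inner] <- 0
  }

  list(activity = activity, material = material, grid = grid, spec = spec)
}

#' Voxelize the NEMA NU 4 mouse-sized count-rate phantom
#'
#' Uniform activity cylinder, 25 mm diameter and 70 mm long by default,
#' centred in the field of view.
#'
#' @param grid a `voxel_grid` covering the phantom
#' @param diameter mm
#' @param length mm
#' @param total_activity_bq total activity; the concentration is set so the
#'   voxelized activity integrates exactly to this value
#' @return list with `activity`, `material`, `grid`
#' @export
build_mouse_phantom <- function(grid, diameter = 25, length = 70,
                                total_activity_bq = 1e6) {
  check_grid_covers(grid, diameter / 2, length / 2, "mouse phantom")
  region <- cylinder_region(c(0, 0, 0), diameter / 2, length)
  mask <- voxelize_region(region, grid)
  if (!any(mask)) stop("mouse phantom voxelizes to an empty volume", call. = FALSE)
  material <- array(MATERIALS[["air"]], grid$shape)
  material[mask] <- MATERIALS[["water"]]
  activity <- array(0, grid$shape)
  activity[mask] <- total_activity_bq / (sum(mask) * voxel_volume_ml(grid))
  list(activity = activity, material = material, grid = grid, region = region)
}

#' Write a volume as NIfTI with a mm affine
#' @param volume numeric array
#' @param grid its `voxel_grid`
#' @param path output file (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
write_volume <- function(volume, grid, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume()]
#' @param path file path
#' @return list with `volume` and `voxel_size`
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = as.array(img), voxel_size = RNifti::pixdim(img))
}

#' Write / read a phantom spec as YAML
#' @param spec an `iq_phantom_spec`
#' @param path file path
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(list(activity_concentration = spec$activity_concentration,
                        wall_thickness = spec$wall_thickness), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  iq_phantom_spec(activity_concentration = x$activity_concentration,
                  wall_thickness = x$wall_thickness)
}
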