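# NEMA NU 4-2008 image-quality metrics: nonuniformity, recovery coefficients,
# spillover ratios, and the tissue-fraction-weighted spillover ratio (wSOR)
# that drives energy-window selection.
#
# SD convention: sample standard deviation (n - 1 denominator) throughout.

#' Standard analysis VOIs for the image-quality phantom
#'
#' Uniform VOI: 22.5 mm diameter x 10 mm long, centred in the uniform region.
#' Cold VOIs: 4 mm diameter x 7.5 mm long, axially centred in each chamber
#' (half the chamber size, limiting positron-range contamination at the
#' edges).
#'
#' @param spec an `iq_phantom_spec`
#' @return named list of `cylinder_region`: `uniform`, `cold_air`,
#'   `cold_water`
#' @export
iq_vois <- function(spec = iq_phantom_spec()) {
  list(
    uniform = cylinder_region(spec$uniform_region$center, 22.5 / 2, 10),
    cold_air = cylinder_region(spec$cold_air$center, 4 / 2, 7.5),
    cold_water = cylinder_region(spec$cold_water$center, 4 / 2, 7.5)
  )
}

#' Nonuniformity (%SD) in the uniform VOI
#'
#' 100 x SD / mean of the voxel values inside the VOI (sample SD).
#'
#' @param image reconstructed volume
#' @param uniform_mask logical VOI mask (same shape), e.g. from
#'   [voxelize_region()]
#' @return percent SD
#' @export
nonuniformity <- function(image, uniform_mask) {
  vals <- image[uniform_mask]
  if (!length(vals)) stop("empty uniform VOI", call. = FALSE)
  m <- mean(vals)
  if (m <= 0) stop("uniform VOI mean must be positive", call. = FALSE)
  100 * stats::sd(vals) / m
}

#' Spillover ratio (%) of a cold compartment
#'
#' 100 x mean(cold VOI) / uniform mean; may be negative after scatter or
#' prompt-gamma subtraction.
#'
#' @param image reconstructed volume
#' @param cold_mask logical VOI mask
#' @param uniform_mean mean of the uniform VOI
#' @return percent
#' @export
spillover_ratio <- function(image, cold_mask, uniform_mean) {
  vals <- image[cold_mask]
  if (!length(vals)) stop("empty cold VOI", call. = FALSE)
  if (uniform_mean <= 0) stop("uniform mean must be positive", call. = FALSE)
  100 * mean(vals) / uniform_mean
}

#' Per-rod recovery coefficients with propagated %SD
#'
#' Standard procedure: average the slices spanning the central 10 mm of the
#' rod section into one transverse image; in a circular ROI of twice each
#' rod's diameter, locate the maximum pixel; extract the axial line profile
#' at that transverse position; RC = mean(profile) / uniform mean (the
#' `"max"` variant instead uses the averaged-image maximum directly). The
#' profile and uniform-region coefficients of variation combine in
#' quadrature:
#' %SD_RC = 100 x sqrt((SD_prof/mean_prof)^2 + (SD_unif/mean_unif)^2).
#'
#' A rod whose averaged-image maximum falls below the uniform-region noise
#' amplitude (`noise_floor_k` x NU/100 x uniform mean) is reported as not
#' discernible (RC and %SD set to NA).
#'
#' @param image reconstructed volume
#' @param grid its `voxel_grid`
#' @param spec the `iq_phantom_spec` (rod positions and diameters)
#' @param uniform_mean,uniform_sd statistics of the uniform VOI
#' @param method "profile" (axial line profile mean) or "max"
#' @param noise_floor_k multiplier on the noise amplitude below which a rod
#'   is declared not discernible (default 3)
#' @param profile_length_mm axial extent of the averaged slices and of the
#'   line profile (default 10 mm, the central portion of the 20 mm rods)
#' @return data.frame with columns `rod_mm`, `rc`, `pct_sd`, `discernible`
#' @export
recovery_coefficients <- function(image, grid, spec, uniform_mean, uniform_sd,
                                  method = c("profile", "max"),
                                  noise_floor_k = 3, profile_length_mm = 10) {
  method <- match.arg(method)
  if (uniform_mean <= 0) stop("uniform mean must be positive", call. = FALSE)
  z <- axis_coords(grid, 3)
  zc <- spec$rod_section$center[3]
  slices <- which(abs(z - zc) <= profile_length_mm / 2)
  if (!length(slices)) stop("no slices cover the rod section", call. = FALSE)
  avg2d <- apply(image[, , slices, drop = FALSE], c(1, 2), mean)
  nu <- 100 * uniform_sd / uniform_mean
  floor_val <- noise_floor_k * nu / 100 * uniform_mean

  x <- axis_coords(grid, 1); y <- axis_coords(grid, 2)
  out <- lapply(spec$rods, function(rod) {
    d_mm <- 2 * rod$radius
    r2 <- outer((x - rod$center[1])^2, (y - rod$center[2])^2, "+")
    roi <- r2 <= (d_mm)^2   # circle of twice the rod diameter
    if (!any(roi)) stop("empty rod ROI", call. = FALSE)
    vals <- avg2d
    vals[!roi] <- -Inf
    peak <- arrayInd(which.max(vals), dim(vals))
    peak_val <- avg2d[peak]
    profile <- image[peak[1], peak[2], slices]
    rc <- switch(method,
                 profile = mean(profile) / uniform_mean,
                 max = peak_val / uniform_mean)
    pct_sd <- 100 * sqrt((stats::sd(profile) / mean(profile))^2 +
                         (uniform_sd / uniform_mean)^2)
    discernible <- peak_val >= floor_val
    data.frame(rod_mm = d_mm, rc = ifelse(discernible, rc, NA_real_),
               pct_sd = ifelse(discernible, pct_sd, NA_real_),
               discernible = discernible)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$rod_mm), ]
}

#' Tissue-fraction-weighted spillover ratio (wSOR)
#'
#' sqrt(f_air x SOR_air^2 + f_water x SOR_water^2), in percent units. The
#' weights are the air (lung) and water volume fractions of a mouse carcass:
#' 0.027 and 0.973.
#'
#' @param sor_air_pct,sor_water_pct spillover ratios in percent
#' @param f_air,f_water non-negative weights summing to 1
#' @return wSOR in percent
#' @export
weighted_sor <- function(sor_air_pct, sor_water_pct,
                         f_air = 0.027, f_water = 0.973) {
  if (f_air < 0 || f_water < 0) stop("weights must be non-negative", call. = FALSE)
  if (abs(f_air + f_water - 1) > 1e-6) stop("weights must sum to 1", call. = FALSE)
  sqrt(f_air * sor_air_pct^2 + f_water * sor_water_pct^2)
}

#' Select the optimal energy window by minimum wSOR
#'
#' Ties are broken toward the wider window (larger ULD), with a message.
#'
#' @param reports data.frame with columns `lld_keV`, `uld_keV`, `wsor`
#' @return the winning `energy_window`
#' @export
select_optimal_window <- function(reports) {
  if (!nrow(reports)) stop("no reports to select from", call. = FALSE)
  best <- min(reports$wsor)
  cand <- reports[reports$wsor == best, , drop = FALSE]
  if (nrow(cand) > 1L) {
    message(sprintf("wSOR tie at %.4g; choosing the wider window", best))
    cand <- cand[which.max(cand$uld_keV), , drop = FALSE]
  }
  energy_window(cand$lld_keV[1], cand$uld_keV[1])
}

#' Full image-quality report for one reconstructed volume
#'
#' @param image reconstructed volume
#' @param grid its `voxel_grid`
#' @param spec the `iq_phantom_spec`
#' @param window the `energy_window` (recorded)
#' @param correction_set label of the applied correction chain
#' @param rc_method passed to [recovery_coefficients()]; NULL skips RCs (e.g.
#'   when the reconstructed slices do not cover the rod section)
#' @return list of class `iq_report`: `window`, `correction_set`,
#'   `nonuniformity_pct`, `rc` (data.frame or NULL), `sor_air_pct`,
#'   `sor_water_pct`, `wsor`
#' @export
iq_report <- function(image, grid, spec, window, correction_set = "AC+SC+PGF",
                      rc_method = "profile") {
  vois <- iq_vois(spec)
  umask <- voxelize_region(vois$uniform, grid)
  uvals <- image[umask]
  umean <- mean(uvals); usd <- stats::sd(uvals)
  nu <- nonuniformity(image, umask)
  sor_air <- spillover_ratio(image, voxelize_region(vois$cold_air, grid), umean)
  sor_water <- spillover_ratio(image, voxelize_region(vois$cold_water, grid), umean)
  rc <- if (!is.null(rc_method)) {
    recovery_coefficients(image, grid, spec, umean, usd, method = rc_method)
  }
  structure(list(window = window, correction_set = correction_set,
                 nonuniformity_pct = nu, rc = rc,
                 sor_air_pct = sor_air, sor_water_pct = sor_water,
                 wsor = weighted_sor(sor_air, sor_water)),
            class = "iq_report")
}

#' @export
print.iq_report <- function(x, ...) {
  cat(sprintf("IQ report [%s, %s]: NU %.2f%%, SOR air %.2f%%, SOR water %.2f%%, wSOR %.2f\n",
              window_label(x$window), x$correction_set, x$nonuniformity_pct,
              x$sor_air_pct, x$sor_water_pct, x$wsor))
  invisible(x)
}
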