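# Isotope physics and acquisition energy windows.

#' Isotope specification
#'
#' @param name character
#' @param half_life_s half-life in seconds
#' @param branching_ratio positron fraction per decay, in (0, 1]
#' @param gamma_lines data.frame with columns `energy_kev`, `intensity`
#'   (fraction per decay) for single cascade gammas (the 511 keV annihilation
#'   photons are implied by the branching ratio)
#' @return an object of class `isotope_spec`
#' @export
isotope_spec <- function(name, half_life_s, branching_ratio,
                         gamma_lines = data.frame(energy_kev = numeric(),
                                                  intensity = numeric())) {
  if (branching_ratio <= 0 || branching_ratio > 1) {
    stop("branching ratio must be in (0, 1]", call. = FALSE)
  }
  if (nrow(gamma_lines) && (any(gamma_lines$intensity < 0) ||
                            any(gamma_lines$intensity > 1))) {
    stop("gamma line intensities must be in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, half_life_s = half_life_s,
                 branching_ratio = branching_ratio, gamma_lines = gamma_lines),
            class = "isotope_spec")
}

#' Built-in isotopes
#'
#' `"I124"`: half-life 4.18 d, branching ratio 23%, cascade gammas at
#' 602 keV (60%), 722 keV (10%) and 1691 keV (11%).
#' `"F18"`: half-life 109.74 min, branching ratio 97%, no cascade gammas.
#'
#' @param name "I124" or "F18"
#' @return an `isotope_spec`
#' @export
isotope <- function(name = c("I124", "F18")) {
  name <- match.arg(name)
  switch(name,
    I124 = isotope_spec("I124", half_life_s = 4.18 * 86400,
                        branching_ratio = 0.23,
                        gamma_lines = data.frame(
                          energy_kev = c(602, 722, 1691),
                          intensity = c(0.60, 0.10, 0.11))),
    F18 = isotope_spec("F18", half_life_s = 109.74 * 60,
                       branching_ratio = 0.97)
  )
}

#' Acquisition energy window
#'
#' @param lld lower level discriminator, keV
#' @param uld upper level discriminator, keV
#' @return an object of class `energy_window`
#' @export
energy_window <- function(lld, uld) {
  stopifnot_scalar(lld, "lld")
  stopifnot_scalar(uld, "uld")
  if (lld <= 0 || uld <= lld) stop("need 0 < lld < uld", call. = FALSE)
  structure(list(lld = lld, uld = uld), class = "energy_window")
}

#' @export
format.energy_window <- function(x, ...) sprintf("%g~%g", x$lld, x$uld)

#' @export
print.energy_window <- function(x, ...) {
  cat("energy window", format(x), "keV\n")
  invisible(x)
}

#' The study's energy windows
#'
#' LLD fixed at 350 keV (to suppress intrinsic lutetium background) with the
#' ULD stepped from 550 to 800 keV in 25 or 50 keV steps, plus the 400~590 keV
#' window used for count-rate comparisons.
#'
#' @return list of `energy_window` objects
#' @export
study_windows <- function() {
  ulds <- c(550, 600, 625, 650, 675, 700, 725, 750, 775, 800)
  c(lapply(ulds, function(u) energy_window(350, u)),
    list(energy_window(400, 590)))
}

#' Label energy windows ("350~750")
#' @param windows a single `energy_window` or a list of them
#' @return character vector
#' @export
window_label <- function(windows) {
  if (inherits(windows, "energy_window")) windows <- list(windows)
  vapply(windows, format, character(1))
}
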