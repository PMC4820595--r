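# Analytic energy-window response model.
#
# The simulator does not transport photons; instead each window's count
# components are scaled by acceptance probabilities computed from a toy
# detected-energy spectrum:
#   * photopeak: 511 keV photons smeared by the detector energy resolution
#     (Gaussian, 14.5% FWHM at 511 keV);
#   * object scatter: scattered 511 keV photons, modeled as a uniform
#     detected-energy continuum between 250 and 540 keV;
#   * cascade gammas: each single-gamma line smeared by the same fractional
#     resolution.
# Trues require both annihilation photons inside the window (photopeak
# acceptance squared); a scatter coincidence pairs one scattered and one
# unscattered photon; randoms scale with the square of the singles rate
# accepted by the window.

gauss_acceptance <- function(window, energy_kev, fwhm_frac = 0.145) {
  sigma <- fwhm_frac * energy_kev / (2 * sqrt(2 * log(2)))
  stats::pnorm(window$uld, energy_kev, sigma) - stats::pnorm(window$lld, energy_kev, sigma)
}

#' Energy-window response factors
#'
#' Computes, for one window, the acceptance probabilities that drive the
#' analytic count model: photopeak acceptance, scatter-continuum acceptance,
#' the relative trues yield (photopeak squared), a window-scaled scatter
#' fraction, and the isotope singles acceptance used to scale randoms.
#'
#' @param window an `energy_window`
#' @param isotope an `isotope_spec` (cascade gamma lines feed the singles
#'   acceptance)
#' @param reference reference window at which the configured scatter fraction
#'   and randoms coefficient are defined (default 350~750 keV)
#' @param scatter_fraction_ref scatter fraction at the reference window
#' @param energy_resolution fractional FWHM at 511 keV
#' @param scatter_spectrum keV range of the detected scatter continuum
#' @param singles_scatter_fraction fraction of detected 511 keV singles that
#'   are scattered (shapes the singles acceptance only)
#' @return list with `photopeak`, `scatter_acceptance`, `trues_rel`,
#'   `scatter_fraction`, `singles_acceptance`, `randoms_scale`
#' @export
window_response <- function(window, isotope = pgfpet::isotope("I124"),
                            reference = energy_window(350, 750),
                            scatter_fraction_ref = 0.10,
                            energy_resolution = 0.145,
                            scatter_spectrum = c(250, 540),
                            singles_scatter_fraction = 0.3) {
  p <- gauss_acceptance(window, 511, energy_resolution)
  p_ref <- gauss_acceptance(reference, 511, energy_resolution)
  sc_acc <- function(w) {
    lo <- max(w$lld, scatter_spectrum[1])
    hi <- min(w$uld, scatter_spectrum[2])
    max(0, hi - lo) / diff(scatter_spectrum)
  }
  s <- sc_acc(window)
  s_ref <- sc_acc(reference)

  # scatter-to-trues count ratio scales as s/p relative to the reference
  sf_ref_ratio <- scatter_fraction_ref / (1 - scatter_fraction_ref)
  ratio <- if (s_ref > 0 && p > 0) sf_ref_ratio * (s / p) / (s_ref / p_ref) else 0
  scatter_fraction <- ratio / (1 + ratio)

  singles <- function(iso) {
    g <- iso$branching_ratio *
      ((1 - singles_scatter_fraction) * p + singles_scatter_fraction * s)
    if (nrow(iso$gamma_lines)) {
      g <- g + sum(iso$gamma_lines$intensity *
                     vapply(iso$gamma_lines$energy_kev,
                            function(e) gauss_acceptance(window, e, energy_resolution),
                            numeric(1)))
    }
    g
  }
  singles_ref <- function(iso) {
    wr <- window_response(reference, iso, reference, scatter_fraction_ref,
                          energy_resolution, scatter_spectrum,
                          singles_scatter_fraction)
    wr$singles_acceptance
  }
  g <- singles(isotope)
  g_ref <- if (identical(format(window), format(reference))) g else singles_ref(isotope)

  list(photopeak = p,
       scatter_acceptance = s,
       trues_rel = (p / p_ref)^2,
       scatter_fraction = scatter_fraction,
       singles_acceptance = g,
       randoms_scale = (g / g_ref)^2)
}
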