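# Published reference tables from the Inveon 124I energy-window study that
# this package reanalyzes. Shipped as plain CSV under inst/extdata; these
# loaders are the supported access path.

ref_path <- function(file) {
  system.file("extdata", file, package = "pgfpet", mustWork = TRUE)
}

#' Published PGF per energy window
#'
#' Prompt gamma coincidence fractions measured on the Inveon scanner for the
#' eleven study windows (LLD 350 keV with ULD 550-800 keV, plus 400~590 keV).
#' Used as the injected ground truth by the simulator and as the lookup table
#' for corrections.
#'
#' @return a `pgf_table`
#' @export
published_pgf_table <- function() {
  read_pgf_table(ref_path("published_pgf_by_window.csv"))
}

#' Published spillover ratios per energy window
#'
#' Measured SOR of the air and nonradioactive-water cold compartments (fully
#' corrected images: attenuation + scatter + prompt gamma) with the published
#' wSOR column, per window.
#'
#' @return data.frame with columns `lld_keV`, `uld_keV`, `sor_air_pct`,
#'   `sor_water_pct`, `wsor`
#' @export
published_sor_table <- function() {
  utils::read.csv(ref_path("published_sor_by_window.csv"))
}

#' Published absolute sensitivities for 124I and 18F
#'
#' Branching-ratio-uncorrected sensitivities (percent) at five representative
#' energy windows, the raw material of the PGF computation.
#'
#' @return data.frame with columns `lld_keV`, `uld_keV`, `s_i124_pct`,
#'   `s_f18_pct`
#' @export
published_sensitivities <- function() {
  utils::read.csv(ref_path("published_sensitivities.csv"))
}
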