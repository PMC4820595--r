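# Synthetic acquisition: per-window sinogram components (trues, scatter,
# randoms, prompt gamma) with the statistical structure the analysis assumes,
# plus sensitivity and count-rate simulations.

#' Acquisition / simulation configuration
#'
#' @param n_angles projection angles over 180 degrees
#' @param n_radial radial bins
#' @param radial_bin_size mm (default matched to the 0.776 mm reconstruction
#'   pixel)
#' @param scatter_fraction scatter fraction (of trues + scatter) at the
#'   reference window
#' @param scatter_sigma_bins radial width (bins) of the Gaussian scatter model
#' @param randoms_coefficient cps/MBq^2 at the reference window (randoms rate
#'   = coefficient x activity^2)
#' @param deadtime_tau non-paralyzable dead time, seconds
#' @param sensitivity absolute coincidence sensitivity per positron at the
#'   reference window (fraction, not percent)
#' @param reference_window window at which `scatter_fraction`,
#'   `randoms_coefficient` and `sensitivity` are defined
#' @param intrinsic_background_cps constant crystal-background coincidence
#'   rate (lutetium radioactivity in the scintillator)
#' @param seed default seed for stochastic operations
#' @return an object of class `acquisition_config`
#' @export
acquisition_config <- function(n_angles = 96,
                               n_radial = 48,
                               radial_bin_size = 0.776,
                               scatter_fraction = 0.10,
                               scatter_sigma_bins = 12,
                               randoms_coefficient = 2000,
                               deadtime_tau = 2e-7,
                               sensitivity = 0.0681,
                               reference_window = energy_window(350, 750),
                               intrinsic_background_cps = 20,
                               seed = 20160322) {
  if (scatter_fraction < 0 || scatter_fraction >= 1) {
    stop("scatter_fraction must be in [0, 1)", call. = FALSE)
  }
  if (deadtime_tau < 0) stop("deadtime_tau must be >= 0", call. = FALSE)
  structure(list(n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 radial_bin_size = radial_bin_size,
                 scatter_fraction = scatter_fraction,
                 scatter_sigma_bins = scatter_sigma_bins,
                 randoms_coefficient = randoms_coefficient,
                 deadtime_tau = deadtime_tau,
                 sensitivity = sensitivity,
                 reference_window = reference_window,
                 intrinsic_background_cps = intrinsic_background_cps,
                 seed = seed),
            class = "acquisition_config")
}

#' Bundle per-component sinograms
#'
#' Holds the noiseless expected trues, scatter, randoms and prompt-gamma
#' sinograms; the expected prompts are their elementwise sum, exactly.
#'
#' @param true_,scatter,random,prompt_gamma non-negative arrays
#'   (angle, radial, slice); scalars are broadcast to the trues shape
#' @param window the `energy_window`
#' @param duration_s acquisition duration
#' @param seed seed recorded for provenance
#' @return an object of class `sinogram_set`
#' @export
sinogram_set <- function(true_, scatter = 0, random = 0, prompt_gamma = 0,
                         window = NULL, duration_s = NA_real_, seed = NA_integer_) {
  d <- dim(true_)
  bc <- function(x) if (length(x) == 1L) array(x, d) else x
  scatter <- bc(scatter); random <- bc(random); prompt_gamma <- bc(prompt_gamma)
  for (comp in list(true_, scatter, random, prompt_gamma)) {
    if (!identical(dim(comp), d)) stop("component shapes differ", call. = FALSE)
    if (any(comp < 0)) stop("sinogram components must be non-negative", call. = FALSE)
  }
  structure(list(true_ = true_, scatter = scatter, random = random,
                 prompt_gamma = prompt_gamma, window = window,
                 duration_s = duration_s, seed = seed),
            class = "sinogram_set")
}

#' Expected prompts sinogram (sum of components)
#' @param ss a `sinogram_set`
#' @export
sinogram_prompts <- function(ss) {
  ss$true_ + ss$scatter + ss$random + ss$prompt_gamma
}

#' Expected trues sinogram for an activity map
#'
#' Forward-projects the activity, applies attenuation, and scales the total
#' to activity x duration x branching ratio x sensitivity x photopeak
#' acceptance squared (both annihilation photons must fall in the window).
#'
#' @param phantom output of [build_iq_phantom()] / [build_mouse_phantom()]
#' @param window the `energy_window`
#' @param duration_s acquisition duration
#' @param isotope an `isotope_spec`
#' @param config an [acquisition_config()]
#' @param count_scale extra multiplier on expected counts (down-scaled study
#'   profiles)
#' @return list with `sinogram` (expected counts), `attenuation` factors and
#'   `total_trues`
#' @export
expected_trues_sinogram <- function(phantom, window, duration_s,
                                    isotope = pgfpet::isotope("I124"),
                                    config = acquisition_config(),
                                    count_scale = 1) {
  shape <- radon_transform(phantom$activity, phantom$grid, config)
  att <- attenuation_factors(phantom$material, phantom$grid, config)
  total_bq <- sum(phantom$activity) * voxel_volume_ml(phantom$grid)
  wr <- window_response(window, isotope, config$reference_window,
                        config$scatter_fraction)
  total_trues <- total_bq * duration_s * isotope$branching_ratio *
    config$sensitivity * wr$trues_rel * count_scale
  if (sum(shape) > 0) shape <- shape * (total_trues / sum(shape))
  list(sinogram = shape * att, attenuation = att, total_trues = total_trues,
       window_response = wr)
}

#' Scatter sinogram component
#'
#' A broad, low-frequency component: the true sinogram blurred radially with
#' a wide Gaussian kernel and rescaled so that
#' mass(scatter)/mass(true) = SF / (1 - SF).
#'
#' @param true_sino expected trues sinogram
#' @param scatter_fraction SF in [0, 1)
#' @param sigma_bins Gaussian width in radial bins (>= 10 for a plausibly
#'   smooth component)
#' @return scatter sinogram, same shape
#' @export
scatter_component <- function(true_sino, scatter_fraction, sigma_bins = 12) {
  if (scatter_fraction < 0 || scatter_fraction >= 1) {
    stop("scatter_fraction must be in [0, 1)", call. = FALSE)
  }
  if (scatter_fraction == 0 || sum(true_sino) == 0) {
    return(array(0, dim(true_sino)))
  }
  blurred <- radial_gaussian_blur(true_sino, sigma_bins)
  target <- scatter_fraction / (1 - scatter_fraction) * sum(true_sino)
  blurred * (target / sum(blurred))
}

#' Prompt-gamma coincidence sinogram component
#'
#' Adds the spurious background from cascade gammas pairing with annihilation
#' photons. Its mass is set so that PG / (trues + scatter + PG) equals the
#' window's PGF. The default spatial model is flat across the field of view
#' (the contamination behaves as spurious background activity); an
#' object-shaped alternative (broadly blurred emission) is available since
#' the true spatial distribution is not pinned down.
#'
#' @param true_sino,scatter_sino expected component sinograms
#' @param pgf prompt gamma coincidence fraction in [0, 1)
#' @param shape "flat" or "object"
#' @return prompt-gamma sinogram, same shape
#' @export
prompt_gamma_component <- function(true_sino, scatter_sino, pgf,
                                   shape = c("flat", "object")) {
  shape <- match.arg(shape)
  if (pgf >= 1 || pgf < 0) stop("pgf must be in [0, 1)", call. = FALSE)
  if (pgf == 0) return(array(0, dim(true_sino)))
  mass <- pgf / (1 - pgf) * (sum(true_sino) + sum(scatter_sino))
  if (shape == "flat") {
    n <- length(true_sino)
    array(mass / n, dim(true_sino))
  } else {
    base <- radial_gaussian_blur(true_sino + scatter_sino, 16)
    base * (mass / sum(base))
  }
}

#' Randoms sinogram component
#'
#' Flat spatial shape; total rate = randoms_coefficient x activity^2 (MBq).
#'
#' @param activity_mbq activity in MBq
#' @param config an [acquisition_config()]
#' @param dims sinogram dimensions (angle, radial, slice)
#' @param duration_s acquisition duration
#' @return randoms sinogram of expected counts
#' @export
randoms_component <- function(activity_mbq, config, dims, duration_s = 1) {
  rate <- config$randoms_coefficient * activity_mbq^2
  array(rate * duration_s / prod(dims), dims)
}

#' Poisson-sample the prompts of a sinogram set
#'
#' Each bin of the expected prompts is replaced by a Poisson draw;
#' reproducible under a fixed seed. The noiseless components are kept.
#'
#' @param ss a `sinogram_set`
#' @param seed integer seed (default: the seed recorded in the set, else the
#'   package default)
#' @return the `sinogram_set` with an added `prompts` element (noisy counts)
#' @export
apply_poisson <- function(ss, seed = NULL) {
  if (is.null(seed)) seed <- if (!is.na(ss$seed)) ss$seed else 20160322
  expected <- sinogram_prompts(ss)
  noisy <- with_seed(seed, stats::rpois(length(expected), as.vector(expected)))
  ss$prompts <- array(as.numeric(noisy), dim(expected))
  ss$seed <- seed
  ss
}

#' Simulate a sensitivity acquisition (line source, low activity)
#'
#' Emulates the paired-isotope sensitivity protocol: a low-activity line
#' source scanned with negligible dead time. Expected trues = activity x
#' branching ratio x geometric sensitivity x window photopeak acceptance^2 x
#' duration (decay-averaged); prompt-gamma counts are added so that their
#' fraction of source coincidences equals `true_pgf` (zero for a pure
#' positron emitter); a constant intrinsic crystal background accrues in both
#' the source scan and a separate background scan.
#'
#' @param isotope an `isotope_spec`
#' @param window the `energy_window`
#' @param true_pgf injected prompt gamma coincidence fraction
#' @param activity_bq source activity at scan start
#' @param duration_s scan duration (default 300 s)
#' @param config an [acquisition_config()]
#' @param background_duration_s duration of the separate background scan
#'   (default 3600 s)
#' @param seed integer seed; NULL for noiseless expected counts
#' @return list with `prompt_counts`, `background_counts`, `duration_s`,
#'   `background_duration_s`, `activity_bq`, `isotope`, `window`
#' @export
simulate_sensitivity_acquisition <- function(isotope, window, true_pgf,
                                             activity_bq, duration_s = 300,
                                             config = acquisition_config(),
                                             background_duration_s = 3600,
                                             seed = NULL) {
  if (true_pgf < 0 || true_pgf >= 1) stop("true_pgf must be in [0, 1)", call. = FALSE)
  wr <- window_response(window, isotope, config$reference_window,
                        config$scatter_fraction)
  # decay-averaged activity over the scan
  lambda <- log(2) / isotope$half_life_s
  mean_activity <- activity_bq * (1 - exp(-lambda * duration_s)) /
    (lambda * duration_s)
  trues_rate <- mean_activity * isotope$branching_ratio *
    config$sensitivity * wr$trues_rel
  pg_rate <- true_pgf / (1 - true_pgf) * trues_rate
  total_rate <- trues_rate + pg_rate + config$intrinsic_background_cps
  loss <- total_rate * config$deadtime_tau / (1 + total_rate * config$deadtime_tau)
  if (loss >= 0.01) {
    warning(sprintf("dead time loss %.1f%% exceeds 1%%: lower the source activity",
                    100 * loss))
  }
  expected_prompt <- total_rate * duration_s
  expected_bg <- config$intrinsic_background_cps * background_duration_s
  if (!is.null(seed)) {
    counts <- with_seed(seed, stats::rpois(2, c(expected_prompt, expected_bg)))
  } else {
    counts <- c(expected_prompt, expected_bg)
  }
  list(prompt_counts = counts[1], background_counts = counts[2],
       duration_s = duration_s, background_duration_s = background_duration_s,
       activity_bq = activity_bq, isotope = isotope, window = window)
}

#' Simulate count rates over an activity range
#'
#' Analytic count model (no Poisson noise by default): trues scale with
#' activity and the window's photopeak acceptance; scatter with the
#' window-scaled scatter fraction; randoms with activity squared and the
#' squared singles acceptance; the prompt-gamma rate follows the window's PGF.
#' All components are throttled by a common non-paralyzable dead-time factor
#' driven by the total incident rate.
#'
#' @param activities_mbq activities in MBq, sorted ascending
#' @param window the `energy_window`
#' @param config an [acquisition_config()]
#' @param isotope an `isotope_spec`
#' @param pgf_table a `pgf_table` giving PGF per window (default: the bundled
#'   reference table)
#' @param noise_seed if non-NULL, Poisson-perturb the rates (1 s frames)
#' @return data.frame of class `count_rates` with columns `activity_mbq`,
#'   `trues`, `scatter`, `randoms`, `prompt_gamma` (cps)
#' @export
simulate_countrates <- function(activities_mbq, window,
                                config = acquisition_config(),
                                isotope = pgfpet::isotope("I124"),
                                pgf_table = published_pgf_table(),
                                noise_seed = NULL) {
  if (any(activities_mbq <= 0)) stop("activities must be positive", call. = FALSE)
  if (is.unsorted(activities_mbq)) stop("activities must be sorted ascending", call. = FALSE)
  wr <- window_response(window, isotope, config$reference_window,
                        config$scatter_fraction)
  pgf <- if (isotope$branching_ratio < 1 && nrow(isotope$gamma_lines) > 0) {
    pgf_for_window(pgf_table, window)
  } else 0
  t_ideal <- activities_mbq * 1e6 * isotope$branching_ratio *
    config$sensitivity * wr$trues_rel
  sf <- wr$scatter_fraction
  s_ideal <- sf / (1 - sf) * t_ideal
  pg_ideal <- pgf / (1 - pgf) * (t_ideal + s_ideal)
  r_ideal <- config$randoms_coefficient * wr$randoms_scale * activities_mbq^2
  total <- t_ideal + s_ideal + pg_ideal + r_ideal
  live <- 1 / (1 + total * config$deadtime_tau)
  rates <- data.frame(activity_mbq = activities_mbq,
                      trues = t_ideal * live,
                      scatter = s_ideal * live,
                      randoms = r_ideal * live,
                      prompt_gamma = pg_ideal * live)
  if (!is.null(noise_seed)) {
    rates[-1] <- with_seed(noise_seed, lapply(rates[-1], function(col) {
      stats::rpois(length(col), col)
    }))
  }
  attr(rates, "window") <- window
  attr(rates, "pgf") <- pgf
  class(rates) <- c("count_rates", "data.frame")
  rates
}

#' Write a sinogram as a raw float array with a JSON metadata sidecar
#'
#' @param sino numeric array (angle, radial, slice)
#' @param path output path for the raw data; the sidecar is `<path>.json`
#' @param config the [acquisition_config()] used
#' @param window the `energy_window` (optional)
#' @param component component name recorded in the sidecar
#' @param extra named list merged into the sidecar (e.g. a correction ledger)
#' @export
write_sinogram <- function(sino, path, config, window = NULL,
                           component = "prompts", extra = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(sino), con, size = 8, endian = "little")
  meta <- c(list(dim = dim(sino),
                 order = c("angle", "radial", "slice"),
                 radial_bin_size_mm = config$radial_bin_size,
                 component = component,
                 window = if (!is.null(window)) window_label(window) else NULL,
                 dtype = "float64-little"),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#' @param path raw-data path (sidecar `<path>.json` must exist)
#' @return list with `sinogram` and `meta`
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- prod(meta$dim)
  vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  list(sinogram = array(vals, meta$dim), meta = meta)
}
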