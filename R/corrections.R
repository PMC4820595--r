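# Sinogram-domain correction chain: normalization, dead time, attenuation,
# scatter / prompt-gamma subtraction, decay. Convention: corrections are
# applied in that order and each is recorded once in a ledger. Negative bins
# produced by subtraction are preserved, never clipped: cold-region spillover
# ratios can legitimately go negative after scatter correction, and clipping
# would bias them upward.

#' Create an empty correction ledger
#' @return an object of class `correction_ledger`
#' @export
correction_ledger <- function() {
  structure(list(), class = "correction_ledger")
}

#' Record an applied correction
#'
#' @param ledger a `correction_ledger`
#' @param name correction name; applying the same correction twice in one
#'   chain is an error
#' @param params named list of parameters, kept for provenance
#' @export
record_correction <- function(ledger, name, params = list()) {
  if (name %in% vapply(ledger, function(e) e$name, character(1))) {
    stop(sprintf("correction '%s' already applied in this chain", name),
         call. = FALSE)
  }
  ledger[[length(ledger) + 1L]] <- list(name = name, params = params)
  class(ledger) <- "correction_ledger"
  ledger
}

#' @export
format.correction_ledger <- function(x, ...) {
  if (!length(x)) return("(no corrections)")
  paste(vapply(x, function(e) e$name, character(1)), collapse = " -> ")
}

#' Normalization
#'
#' Elementwise division by detector-efficiency factors. In synthetic mode the
#' factors default to 1 (the simulator has no efficiency pattern).
#'
#' @param emission_sino emission sinogram
#' @param norm_sino positive efficiency factors, same shape (or scalar)
#' @export
normalize_sinogram <- function(emission_sino, norm_sino = 1) {
  if (any(norm_sino <= 0)) stop("normalization factors must be positive", call. = FALSE)
  emission_sino / norm_sino
}

#' Non-paralyzable dead-time correction
#'
#' Inverts the non-paralyzable rate loss: R = R_obs / (1 - R_obs * tau).
#'
#' @param observed_rate observed rate (cps) or counts scaled by a known rate
#' @param tau dead time in seconds
#' @export
deadtime_correct <- function(observed_rate, tau) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (any(observed_rate * tau >= 1)) {
    stop("observed rate times tau must be < 1 for the non-paralyzable inversion",
         call. = FALSE)
  }
  observed_rate / (1 - observed_rate * tau)
}

#' Attenuation correction
#'
#' Elementwise division of the emission sinogram by the coincidence survival
#' factors (in (0, 1]); total mass increases.
#'
#' @param emission_sino emission sinogram
#' @param attenuation_sino factors from [attenuation_factors()]
#' @export
attenuation_correct <- function(emission_sino, attenuation_sino) {
  if (!identical(dim(emission_sino), dim(attenuation_sino))) {
    stop("shape mismatch between emission and attenuation sinograms", call. = FALSE)
  }
  if (any(attenuation_sino <= 0) || any(attenuation_sino > 1)) {
    stop("attenuation factors must lie in (0, 1]", call. = FALSE)
  }
  emission_sino / attenuation_sino
}

#' Estimate the scatter sinogram
#'
#' `"truth"` returns the simulator's stored scatter component (useful for
#' isolating downstream behavior in tests). `"tail_fit"` fits, per slice, a
#' Gaussian in the radial coordinate to the angle-averaged emission in the
#' bins outside the object support, and interpolates it under the object —
#' the standard tail-fitting idea behind scatter estimation when no model
#'-based estimate is available.
#'
#' @param emission_sino emission sinogram (angle, radial, slice)
#' @param method "truth" or "tail_fit"
#' @param ss the `sinogram_set` holding the stored component (truth mode)
#' @param config an [acquisition_config()] (tail_fit mode, for radial coords)
#' @param object_radius_mm radial extent of the object support (tail_fit)
#' @param margin_bins extra bins beyond the object radius excluded from the
#'   tail fit
#' @return scatter sinogram, same shape as the emission
#' @export
estimate_scatter <- function(emission_sino, method = c("truth", "tail_fit"),
                             ss = NULL, config = NULL, object_radius_mm = NULL,
                             margin_bins = 0) {
  method <- match.arg(method)
  if (method == "truth") {
    if (is.null(ss)) stop("truth mode needs the sinogram_set", call. = FALSE)
    return(ss$scatter)
  }
  if (is.null(config) || is.null(object_radius_mm)) {
    stop("tail_fit mode needs 'config' and 'object_radius_mm'", call. = FALSE)
  }
  if (any(emission_sino < 0)) emission_sino[emission_sino < 0] <- 0
  if (sum(emission_sino) == 0) return(array(0, dim(emission_sino)))
  s <- radial_coords(config)
  support <- abs(s) <= object_radius_mm + margin_bins * config$radial_bin_size
  if (all(support)) stop("no radial bins outside the object support", call. = FALSE)
  d <- dim(emission_sino)
  out <- array(0, d)
  for (sl in seq_len(d[3])) {
    prof <- colMeans(emission_sino[, , sl, drop = FALSE][, , 1])
    tail_idx <- which(!support & prof > 0)
    if (length(tail_idx) < 3L) {
      stop("too few positive out-of-object bins for the tail fit", call. = FALSE)
    }
    df <- data.frame(y = log(prof[tail_idx]), s = s[tail_idx],
                     w = prof[tail_idx])
    # weights ~ counts: log-scale variance of a Poisson profile is ~1/counts
    fit <- stats::lm(y ~ s + I(s^2), data = df, weights = w)
    co <- stats::coef(fit)
    if (!is.finite(co[3]) || co[3] >= 0) {
      # degenerate (non-decaying) fit: fall back to the mean tail level
      pred <- rep(mean(prof[tail_idx]), length(s))
    } else {
      pred <- exp(co[1] + co[2] * s + co[3] * s^2)
    }
    out[, , sl] <- matrix(pred, d[1], d[2], byrow = TRUE)
  }
  out
}

#' Prompt gamma coincidence correction
#'
#' Subtracts the window's prompt-gamma contamination using the scatter
#' estimate as its spatial template:
#' corrected = emission - scatter x PGF (elementwise). With
#' `subtract_scatter = TRUE` the scatter estimate itself is also removed
#' (corrected = emission - scatter x (1 + PGF)), giving the nested
#' attenuation + scatter + prompt-gamma correction set in one call.
#' Negative bins are preserved.
#'
#' @param emission_sino emission sinogram
#' @param scatter_sino scatter estimate, same shape
#' @param pgf prompt gamma coincidence fraction in [0, 1)
#' @param subtract_scatter also subtract the scatter estimate itself
#' @export
prompt_gamma_correct <- function(emission_sino, scatter_sino, pgf,
                                 subtract_scatter = FALSE) {
  if (pgf < 0 || pgf >= 1) stop("pgf must be in [0, 1)", call. = FALSE)
  if (!identical(dim(emission_sino), dim(scatter_sino))) {
    stop("shape mismatch between emission and scatter sinograms", call. = FALSE)
  }
  emission_sino - scatter_sino * (pgf + as.numeric(subtract_scatter))
}

#' Decay correction
#'
#' Rescales counts to the reference time: counts x 2^(elapsed / half-life).
#'
#' @param counts counts or rates
#' @param elapsed_s time since the reference, seconds (>= 0)
#' @param isotope an `isotope_spec`
#' @export
decay_correct <- function(counts, elapsed_s, isotope) {
  if (elapsed_s < 0) stop("elapsed time must be >= 0", call. = FALSE)
  counts * 2^(elapsed_s / isotope$half_life_s)
}

#' Apply the standard correction chain to a noisy acquisition
#'
#' Order: normalization -> dead time -> attenuation -> randoms subtraction ->
#' scatter / prompt-gamma subtraction -> decay. Randoms are subtracted as
#' their known expectation (the simulator's stored component). Which of the
#' scatter and prompt-gamma subtractions run is governed by `correction_set`:
#' `"AC"` (attenuation only), `"AC+SC"` (plus scatter subtraction) or
#' `"AC+SC+PGF"` (plus prompt-gamma subtraction).
#'
#' @param ss a `sinogram_set` that has been through [apply_poisson()]
#' @param attenuation attenuation factor sinogram
#' @param pgf the window's prompt gamma coincidence fraction
#' @param correction_set "AC", "AC+SC" or "AC+SC+PGF"
#' @param scatter_method "truth" or "tail_fit" (see [estimate_scatter()])
#' @param config,object_radius_mm passed to [estimate_scatter()] in tail_fit
#'   mode
#' @param norm_sino normalization factors (default 1)
#' @return list with `sinogram` (corrected emission) and `ledger`
#' @export
correct_emission <- function(ss, attenuation, pgf,
                             correction_set = c("AC+SC+PGF", "AC+SC", "AC"),
                             scatter_method = "truth", config = NULL,
                             object_radius_mm = NULL, norm_sino = 1) {
  correction_set <- match.arg(correction_set)
  if (is.null(ss$prompts)) stop("apply_poisson() first", call. = FALSE)
  ledger <- correction_ledger()

  emission <- normalize_sinogram(ss$prompts, norm_sino)
  ledger <- record_correction(ledger, "normalization", list(uniform = all(norm_sino == 1)))

  # dead time: the simulator applies no rate loss inside a frame, so the
  # correction factor is 1; recorded for the order contract.
  ledger <- record_correction(ledger, "dead_time", list(tau_s = 0))

  emission <- emission - ss$random
  ledger <- record_correction(ledger, "randoms_subtraction", list(mode = "expectation"))

  emission <- attenuation_correct(emission, attenuation)
  ledger <- record_correction(ledger, "attenuation", list())

  if (correction_set %in% c("AC+SC", "AC+SC+PGF")) {
    scatter_raw <- estimate_scatter(ss$prompts - ss$random, scatter_method,
                                    ss = ss, config = config,
                                    object_radius_mm = object_radius_mm)
    scatter <- attenuation_correct(scatter_raw, attenuation)
    with_pg <- correction_set == "AC+SC+PGF"
    emission <- prompt_gamma_correct(emission, scatter,
                                     pgf = if (with_pg) pgf else 0,
                                     subtract_scatter = TRUE)
    ledger <- record_correction(ledger, "scatter", list(method = scatter_method))
    if (with_pg) ledger <- record_correction(ledger, "prompt_gamma", list(pgf = pgf))
  }

  ledger <- record_correction(ledger, "decay", list(elapsed_s = 0))
  list(sinogram = emission, ledger = ledger)
}
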