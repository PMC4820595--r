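# Prompt gamma coincidence fraction (PGF) from paired isotope sensitivities.
#
# The high-energy cascade gammas of a non-pure positron emitter inflate its
# measured sensitivity relative to what its positron yield alone supports.
# Comparing the branching-ratio-corrected sensitivity of the cascade emitter
# (124I) with a prompt-gamma-free reference (18F) therefore isolates the
# fraction of recorded coincidences caused by prompt gammas:
#
#   PGF = (S_I124^corr - S_F18^corr) / S_I124^corr,  S^corr = S / BR.

#' Absolute sensitivity from a sensitivity acquisition
#'
#' S (%) = 100 x (prompt counts - background rate x duration) /
#' (duration x decay rate). The background is measured in a separate long
#' scan and subtracted at its rate. If an isotope is supplied the activity is
#' decay-averaged over the scan; otherwise it is treated as constant.
#' Negative net counts are floored at zero with a warning.
#'
#' @param prompt_counts total prompt counts in the source scan
#' @param background_counts counts in the background scan
#' @param duration_s source scan duration
#' @param activity_bq source activity at scan start (decays/s)
#' @param background_duration_s background scan duration (default 3600 s)
#' @param isotope optional `isotope_spec` for decay averaging
#' @return sensitivity in percent
#' @export
absolute_sensitivity <- function(prompt_counts, background_counts, duration_s,
                                 activity_bq, background_duration_s = 3600,
                                 isotope = NULL) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  if (activity_bq <= 0) stop("activity must be positive", call. = FALSE)
  net <- prompt_counts - background_counts / background_duration_s * duration_s
  if (net < 0) {
    warning("net counts below zero after background subtraction; floored at 0")
    net <- 0
  }
  mean_activity <- activity_bq
  if (!is.null(isotope)) {
    lambda <- log(2) / isotope$half_life_s
    mean_activity <- activity_bq * (1 - exp(-lambda * duration_s)) /
      (lambda * duration_s)
  }
  100 * net / (duration_s * mean_activity)
}

#' Branching-ratio correction of a sensitivity
#'
#' Divides the measured (branching-ratio-uncorrected) sensitivity by the
#' isotope's positron branching ratio, putting isotopes with different
#' positron yields on a per-positron scale.
#'
#' @param sensitivity_pct measured sensitivity in percent
#' @param isotope an `isotope_spec` (or a numeric branching ratio)
#' @return corrected sensitivity in percent
#' @export
branching_ratio_correct <- function(sensitivity_pct, isotope) {
  br <- if (inherits(isotope, "isotope_spec")) isotope$branching_ratio else isotope
  if (br <= 0) stop("branching ratio must be positive", call. = FALSE)
  sensitivity_pct / br
}

#' Prompt gamma coincidence fraction from paired corrected sensitivities
#'
#' PGF = (S_I124 - S_F18) / S_I124, both branching-ratio corrected, treating
#' 18F as the prompt-gamma-free reference. A negative value (reference more
#' sensitive than the cascade emitter) is clipped to 0 with a warning.
#'
#' @param s_i124_corrected branching-ratio-corrected 124I sensitivity (%)
#' @param s_f18_corrected branching-ratio-corrected 18F sensitivity (%)
#' @return PGF as a fraction in [0, 1)
#' @export
compute_pgf <- function(s_i124_corrected, s_f18_corrected) {
  if (s_i124_corrected <= 0) stop("124I sensitivity must be positive", call. = FALSE)
  pgf <- (s_i124_corrected - s_f18_corrected) / s_i124_corrected
  if (pgf < 0) {
    warning("negative PGF clipped to 0")
    pgf <- 0
  }
  pgf
}

#' Build a PGF-per-window table
#'
#' @param lld,uld keV vectors
#' @param pgf PGF fractions in [0, 1)
#' @return data.frame of class `pgf_table` with columns `lld_keV`, `uld_keV`,
#'   `pgf`
#' @export
pgf_table <- function(lld, uld, pgf) {
  if (any(pgf < 0 | pgf >= 1)) stop("PGF values must be in [0, 1)", call. = FALSE)
  if (any(uld <= lld)) stop("need uld > lld", call. = FALSE)
  tab <- data.frame(lld_keV = lld, uld_keV = uld, pgf = pgf)
  tab <- tab[order(tab$lld_keV, tab$uld_keV), ]
  rownames(tab) <- NULL
  class(tab) <- c("pgf_table", "data.frame")
  tab
}

#' Look up (or interpolate) the PGF for a window
#'
#' Exact matches are returned directly; otherwise the PGF is linearly
#' interpolated in ULD among table rows sharing the window's LLD.
#' Extrapolation beyond the tabulated ULD range is clamped to the endpoint
#' with a warning. A window whose LLD has no table rows is an error.
#'
#' @param table a `pgf_table`
#' @param window an `energy_window`
#' @return PGF fraction
#' @export
pgf_for_window <- function(table, window) {
  if (!nrow(table)) stop("empty PGF table", call. = FALSE)
  exact <- table$lld_keV == window$lld & table$uld_keV == window$uld
  if (any(exact)) return(table$pgf[which(exact)[1]])
  rows <- table[table$lld_keV == window$lld, ]
  if (!nrow(rows)) {
    stop(sprintf("no PGF entries with LLD %g keV and no exact match", window$lld),
         call. = FALSE)
  }
  if (window$uld < min(rows$uld_keV) || window$uld > max(rows$uld_keV)) {
    warning("ULD outside tabulated range; clamped to the nearest endpoint")
    return(rows$pgf[which.min(abs(rows$uld_keV - window$uld))])
  }
  if (nrow(rows) == 1L) return(rows$pgf)
  stats::approx(rows$uld_keV, rows$pgf, xout = window$uld)$y
}

#' Write / read a PGF table as CSV (columns lld_keV, uld_keV, pgf)
#' @param table a `pgf_table`
#' @param path file path
#' @export
write_pgf_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pgf_table
#' @export
read_pgf_table <- function(path) {
  x <- utils::read.csv(path)
  pgf_table(x$lld_keV, x$uld_keV, x$pgf)
}

#' Zero-attenuation extrapolation over aluminum sleeves
#'
#' The NEMA NU 2 sensitivity protocol encases the line source in 1..n
#' aluminum sleeves and extrapolates the count rate to zero sleeve thickness
#' with a log-linear fit, removing source self-attenuation.
#'
#' @param rates count rates (cps), one per sleeve configuration
#' @param thickness_mm total sleeve thickness for each rate
#' @return extrapolated attenuation-free rate (cps)
#' @export
sleeve_zero_extrapolation <- function(rates, thickness_mm) {
  if (length(rates) < 2L) stop("need at least two sleeve measurements", call. = FALSE)
  if (any(rates <= 0)) stop("rates must be positive for a log-linear fit", call. = FALSE)
  fit <- stats::lm(log(rates) ~ thickness_mm)
  exp(unname(stats::coef(fit)[1]))
}

#' Estimate a PGF table from simulated paired-isotope acquisitions
#'
#' Runs the full estimation chain per window: simulate a 124I and an 18F
#' sensitivity acquisition, convert counts to absolute sensitivities, apply
#' the branching-ratio correction, and form the PGF.
#'
#' @param windows list of `energy_window`
#' @param true_table `pgf_table` of injected PGFs
#' @param config an [acquisition_config()]
#' @param activity_i124_bq,activity_f18_bq source activities (defaults: the
#'   protocol's 506 and 673 kBq)
#' @param duration_s scan duration (default 300 s)
#' @param seed integer seed; NULL for noiseless
#' @return a `pgf_table` of estimates
#' @export
estimate_pgf_table <- function(windows, true_table = published_pgf_table(),
                               config = acquisition_config(),
                               activity_i124_bq = 506e3,
                               activity_f18_bq = 673e3,
                               duration_s = 300, seed = NULL) {
  i124 <- isotope("I124"); f18 <- isotope("F18")
  est <- vapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    true_pgf <- pgf_for_window(true_table, w)
    sd_i <- if (is.null(seed)) NULL else seed + 2L * i
    sd_f <- if (is.null(seed)) NULL else seed + 2L * i + 1L
    acq_i <- simulate_sensitivity_acquisition(i124, w, true_pgf,
                                              activity_i124_bq, duration_s,
                                              config, seed = sd_i)
    acq_f <- simulate_sensitivity_acquisition(f18, w, 0,
                                              activity_f18_bq, duration_s,
                                              config, seed = sd_f)
    s_i <- absolute_sensitivity(acq_i$prompt_counts, acq_i$background_counts,
                                duration_s, activity_i124_bq,
                                acq_i$background_duration_s, i124)
    s_f <- absolute_sensitivity(acq_f$prompt_counts, acq_f$background_counts,
                                duration_s, activity_f18_bq,
                                acq_f$background_duration_s, f18)
    compute_pgf(branching_ratio_correct(s_i, i124),
                branching_ratio_correct(s_f, f18))
  }, numeric(1))
  pgf_table(vapply(windows, function(w) w$lld, numeric(1)),
            vapply(windows, function(w) w$uld, numeric(1)),
            est)
}
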