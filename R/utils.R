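# Small internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulator calls do not perturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' 1-D Gaussian convolution along the radial axis of a sinogram
#'
#' Convolves each (angle, slice) radial profile with a normalized Gaussian
#' kernel, zero-padded at the edges. Used by the scatter model.
#' @param sino array (angle, radial, slice)
#' @param sigma_bins kernel standard deviation in radial bins
#' @return array of the same shape
#' @keywords internal
radial_gaussian_blur <- function(sino, sigma_bins) {
  if (sigma_bins <= 0) return(sino)
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  d <- dim(sino)
  out <- array(0, d)
  for (sl in seq_len(d[3])) {
    for (a in seq_len(d[1])) {
      p <- sino[a, , sl]
      padded <- c(numeric(half), p, numeric(half))
      conv <- stats::filter(padded, k, method = "convolution", sides = 2)
      out[a, , sl] <- conv[(half + 1):(half + d[2])]
    }
  }
  out
}

#' @keywords internal
stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
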