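# Internal numerical helpers shared across modules.

#' Wrap phase differences into (-pi, pi]
#'
#' @param d numeric vector or matrix of phase differences in radians.
#' @return values wrapped to the principal interval `(-pi, pi]`.
#' @keywords internal
wrap_phase <- function(d) {
  w <- d %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Analytic signal via the frequency domain
#'
#' Computes the complex analytic extension of each column of `x` (real
#' narrowband signals) by zeroing negative frequencies and doubling positive
#' ones. The angle of the result is the instantaneous phase.
#'
#' @param x numeric vector or samples-by-series matrix.
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) abort("analytic_signal() needs at least 2 samples.")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- mvfft(mvfft(x) * h, inverse = TRUE) / n
  if (vec) a[, 1] else a
}

# Zero-phase Butterworth filtering of each column of a samples-by-series
# matrix (or a vector): designed in second-order sections, each biquad
# applied forward-backward with short odd-reflection padding and
# steady-state initial conditions (the scipy filtfilt recipe). `w` is
# normalized to Nyquist.
zp_butter <- function(x, w, type, order = 4, padlen = NULL) {
  sos_filtfilt(x, butter_sos(order, w, type), padlen = padlen)
}

# Draw independent sub-seeds from a master seed without touching the caller's
# RNG state (counter scheme: one master stream, one draw per consumer).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}
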