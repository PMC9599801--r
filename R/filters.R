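# Butterworth design in second-order sections (biquad cascade).
#
# High-order IIR filters with poles very close to the unit circle (a 0.1 Hz
# high-pass at 1000 Hz, a narrow 48-52 Hz band-stop) lose precision badly in
# single transfer-function form: the polynomial coefficients encode the poles
# only up to catastrophic cancellation, and recursion error grows along the
# signal. A cascade of second-order sections stores each conjugate pole pair
# directly and stays accurate, which is why it is the standard realisation
# for EEG-grade filtering.

# Analog Butterworth prototype poles (unit cutoff, left half-plane).
butter_prototype <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

#' Design a zero-phase-ready Butterworth filter as second-order sections
#'
#' @param order prototype order (the band-pass/band-stop cascade has 2x the
#'   states, as usual).
#' @param w critical frequency(ies) normalized to Nyquist (in (0, 1)); one
#'   value for `low`/`high`, two for `pass`/`stop`.
#' @param type filter type.
#' @return matrix with 6 columns (b0, b1, b2, a0, a1, a2), one row per
#'   biquad section.
#' @keywords internal
butter_sos <- function(order, w, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) abort("Normalized frequencies must be in (0, 1).")
  p_proto <- butter_prototype(order)
  warped <- tan(pi * w / 2)

  if (type == "low") {
    poles <- warped * p_proto
    zeros <- complex(0)
    gain <- warped^order
  } else if (type == "high") {
    poles <- warped / p_proto
    zeros <- rep(0 + 0i, order)
    gain <- 1
  } else {
    w0 <- sqrt(prod(warped))
    bw <- warped[2] - warped[1]
    if (type == "pass") {
      # s -> (s^2 + w0^2) / (bw * s)
      poles <- unlist(lapply(p_proto, function(p) {
        disc <- sqrt(as.complex((p * bw)^2 / 4 - w0^2))
        c(p * bw / 2 + disc, p * bw / 2 - disc)
      }))
      zeros <- rep(0 + 0i, order)
      gain <- bw^order
    } else {
      # s -> bw * s / (s^2 + w0^2)
      poles <- unlist(lapply(p_proto, function(p) {
        disc <- sqrt(as.complex((bw / p)^2 / 4 - w0^2))
        c(bw / (2 * p) + disc, bw / (2 * p) - disc)
      }))
      zeros <- rep(c(1i * w0, -1i * w0), order)
      gain <- 1
    }
  }

  # bilinear transform z = (1 + s) / (1 - s)
  z_poles <- (1 + poles) / (1 - poles)
  z_zeros <- (1 + zeros) / (1 - zeros)
  gain <- gain * Re(prod(1 - zeros) / prod(1 - poles))
  # pole excess maps to zeros at z = -1
  n_extra <- length(z_poles) - length(z_zeros)
  z_zeros <- c(z_zeros, rep(-1 + 0i, n_extra))

  # Pair conjugate poles into sections (sorted by distance to the unit
  # circle so the most delicate sections are explicit biquads), and give
  # every section a conjugate/zero pair. Butterworth zeros are all
  # identical (or one conjugate pair repeated), so pairing is direct.
  take_conj_pairs <- function(v) {
    pairs <- list()
    v <- v[order(abs(1 - abs(v)), Im(v))]
    used <- rep(FALSE, length(v))
    for (i in seq_along(v)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(v[i])) < 1e-12) {
        j <- which(!used & abs(Im(v)) < 1e-12)[1]
        if (is.na(j)) {
          pairs[[length(pairs) + 1]] <- v[i]  # lone real root
          next
        }
      } else {
        j <- which(!used & abs(v - Conj(v[i])) < 1e-8 * (1 + abs(v[i])))[1]
        if (is.na(j)) j <- which(!used)[1]
      }
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(v[i], v[j])
      }
    pairs
  }
  pole_pairs <- take_conj_pairs(z_poles)
  zero_pairs <- take_conj_pairs(z_zeros)
  n_sec <- length(pole_pairs)

  poly2 <- function(roots) {
    # real quadratic (or linear) from a root set
    cf <- Re(c(1, -sum(roots), if (length(roots) == 2) prod(roots) else NULL))
    c(cf, rep(0, 3 - length(cf)))
  }
  sos <- matrix(0, n_sec, 6)
  for (s in seq_len(n_sec)) {
    zp <- if (s <= length(zero_pairs)) zero_pairs[[s]] else complex(0)
    sos[s, 1:3] <- poly2(zp)
    sos[s, 4:6] <- poly2(pole_pairs[[s]])
  }
  sos[1, 1:3] <- sos[1, 1:3] * gain
  sos
}

# Zero-phase filtering through a biquad cascade: each section is applied
# forward-backward (cpp kernel) with odd-reflection padding, so the cascade
# as a whole has zero phase and the squared magnitude of the design.
sos_filtfilt <- function(x, sos, padlen = NULL) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  padlen <- as.integer(min(padlen %||% 12L, nrow(x) - 1L))
  if (nrow(x) < 4) abort("Signal too short to filter.")
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3] / sos[s, 4]
    a <- sos[s, 4:6] / sos[s, 4]
    x <- cpp_filtfilt(b, a, x, padlen)
  }
  if (vec) x[, 1] else x
}
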