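# Small builders shared across test files. Everything is generated in code;
# sizes are kept small so the default run stays fast.

# A light recording spec: few channels, modest rate, white noise by default
# (cheapest and easiest to reason about in unit tests).
quick_spec <- function(n_channels = 4, sampling_rate = 128, duration = 30,
                       kappa_alpha = 1, noise_sd = 10, ...) {
  osc <- tibble::tibble(name = "alpha", center = 10.5, bandwidth = 5,
                        kappa = kappa_alpha)
  recording_spec(
    n_channels = n_channels, sampling_rate = sampling_rate,
    duration = duration, oscillator_bands = osc, noise_sd = noise_sd,
    noise_color = "white", regional_gain = 1, ...
  )
}

# Recording built from an explicit channels-by-samples matrix.
matrix_recording <- function(data, fs = 128, labels = NULL) {
  if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(data)))
  eeg_recording(data, labels, fs)
}

# Single sinusoid recording across n_channels identical channels.
sine_recording <- function(freq, fs = 1000, duration = 10, n_channels = 1,
                           amplitude = 1, phase = 0) {
  t <- (seq_len(fs * duration) - 1) / fs
  x <- amplitude * sin(2 * pi * freq * t + phase)
  matrix_recording(matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE),
                   fs = fs)
}

# RMS of the central portion of a signal (avoids residual edge effects).
mid_rms <- function(x, frac = 0.6) {
  n <- length(x)
  lo <- floor(n * (1 - frac) / 2) + 1
  sqrt(mean(x[lo:(lo + floor(n * frac) - 1)]^2))
}

# Hand-built pli_matrix from a symmetric values matrix (for tests that
# need connectivity inputs without synthesising EEG).
fixture_pli_matrix <- function(values, labels = NULL, band = "alpha") {
  if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  eegpli:::new_pli_matrix(values, eegpli:::get_band(band), labels, 1L)
}

# Random symmetric PLI-like matrix with zero diagonal, entries in [0, 1].
random_pli_values <- function(n_channels, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n_channels^2), n_channels)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
}

# Connectivity tibble (as from cohort_connectivity) built from fixture
# matrices: one alpha matrix per subject, values N(center_g, sd) per pair.
fixture_conn <- function(n_per_group, n_channels, center_mci, center_nc,
                         sd = 0.02, seed = 1) {
  ids <- sprintf("sub%03d", seq_len(2 * n_per_group))
  groups <- rep(c("MCI", "NC"), each = n_per_group)
  withr::with_seed(seed, {
    rows <- lapply(seq_along(ids), function(i) {
      center <- if (groups[i] == "MCI") center_mci else center_nc
      v <- matrix(0, n_channels, n_channels)
      vals <- pmin(1, pmax(0, stats::rnorm(choose(n_channels, 2), center, sd)))
      v[upper.tri(v)] <- vals
      v <- v + t(v)
      cm <- fixture_pli_matrix(v)
      tibble::tibble(subject_id = ids[i], band = "alpha", matrix = list(cm),
                     global_pli = global_pli(cm))
    })
  })
  list(
    conn = dplyr::bind_rows(rows),
    cohort = tibble::tibble(subject_id = ids, group = groups)
  )
}
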