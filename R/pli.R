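# Phase lag index connectivity.
#
# PLI between two signals = |< sign(dphi(t_k)) >| over phase samples k, with
# dphi the instantaneous phase difference wrapped to (-pi, pi] and
# sign(0) = 0. It is 0 when phase differences are symmetric around zero
# (no coupling, or zero-lag/volume-conducted coupling) and 1 when one signal
# consistently leads or lags the other.

#' Classical EEG frequency bands
#'
#' @return tibble with columns `name`, `low`, `high` (Hz): delta 1-4,
#'   theta 4-8, alpha 8-13, beta 13-30.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    name = c("delta", "theta", "alpha", "beta"),
    low = c(1, 4, 8, 13),
    high = c(4, 8, 13, 30)
  )
}

get_band <- function(band) {
  if (is.character(band)) {
    hit <- dplyr::filter(eeg_bands(), .data$name == band)
    if (nrow(hit) != 1) abort(sprintf("Unknown band `%s`.", band))
    return(hit)
  }
  stopifnot(is.data.frame(band), all(c("name", "low", "high") %in% names(band)),
            nrow(band) == 1)
  if (band$low >= band$high) abort("Band must have low < high.")
  band
}

#' Instantaneous phase of band-filtered epochs
#'
#' Each epoch/channel is band-filtered with a zero-phase fourth-order
#' Butterworth band-pass, converted to instantaneous phase via the analytic
#' signal, and trimmed by `edge_trim` of the samples at each epoch end to
#' suppress filter and analytic-signal edge artifacts.
#'
#' @param es an [eeg_epochs()] object.
#' @param band band name (`"delta"`, `"theta"`, `"alpha"`, `"beta"`) or a
#'   one-row tibble with `name`, `low`, `high`.
#' @param edge_trim fraction of samples removed from each epoch end
#'   (default 0.1, in `[0, 0.5)`).
#' @return a `phase_series`: list with `phases` (sample x channel x epoch
#'   array of radians in (-pi, pi]), `band`, `channel_labels`,
#'   `sampling_rate`.
#' @export
band_phase <- function(es, band = "alpha", edge_trim = 0.1) {
  stopifnot(inherits(es, "eeg_epochs"))
  band <- get_band(band)
  if (edge_trim < 0 || edge_trim >= 0.5) abort("`edge_trim` must be in [0, 0.5).")
  nyq <- es$sampling_rate / 2
  if (band$high >= nyq) abort("Band upper edge must be below the Nyquist frequency.")

  d <- dim(es$epochs)  # epoch x channel x sample
  n_ep <- d[1]; n_ch <- d[2]; n_s <- d[3]
  # Stack all epoch-channels as columns: one filter call, one FFT batch.
  x <- matrix(aperm(es$epochs, c(3, 2, 1)), nrow = n_s, ncol = n_ch * n_ep)
  if (max(abs(x)) == 0) abort("Zero signal: instantaneous phase is undefined.")
  x <- zp_butter(x, c(band$low, band$high) / nyq, "pass")
  ph <- Arg(analytic_signal(x))
  trim <- floor(edge_trim * n_s)
  keep <- (trim + 1):(n_s - trim)
  ph <- array(ph[keep, ], c(length(keep), n_ch, n_ep))
  structure(
    list(
      phases = ph,
      band = band,
      channel_labels = es$channel_labels,
      sampling_rate = es$sampling_rate
    ),
    class = "phase_series"
  )
}

#' Phase lag index of one channel pair
#'
#' `|mean_k sign(dphi_k)|` with `dphi` wrapped to `(-pi, pi]` and
#' `sign(0) = 0`.
#'
#' @param phase_i,phase_j equal-length numeric vectors of instantaneous
#'   phase (radians).
#' @return PLI in `[0, 1]`.
#' @export
pli_pair <- function(phase_i, phase_j) {
  if (length(phase_i) < 1 || length(phase_i) != length(phase_j)) {
    abort("Phase sequences must be non-empty and of equal length.")
  }
  abs(mean(sign(wrap_phase(phase_i - phase_j))))
}

#' Band-specific PLI connectivity matrix
#'
#' PLI is computed for every unordered channel pair within each epoch, then
#' averaged across epochs (set `aggregate = "pooled"` to pool all phase
#' samples into a single estimate instead).
#'
#' @inheritParams band_phase
#' @param aggregate `"epochs"` (per-epoch PLI averaged across epochs, the
#'   default) or `"pooled"` (one PLI over all concatenated samples).
#' @return a `pli_matrix`: list with `values` (symmetric channel x channel
#'   matrix, zero diagonal, entries in `[0, 1]`), `band`, `channel_labels`,
#'   `n_epochs_averaged`.
#' @export
connectivity_matrix <- function(es, band = "alpha", edge_trim = 0.1,
                                aggregate = c("epochs", "pooled")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(es, "eeg_epochs"))
  if (length(es$channel_labels) < 2) abort("At least 2 channels are required.")
  ps <- band_phase(es, band, edge_trim)
  d <- dim(ps$phases)
  if (aggregate == "pooled") {
    flat <- matrix(aperm(ps$phases, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
    values <- cpp_pli_matrix(flat)
  } else {
    values <- matrix(0, d[2], d[2])
    for (e in seq_len(d[3])) values <- values + cpp_pli_matrix(ps$phases[, , e])
    values <- values / d[3]
  }
  dimnames(values) <- list(ps$channel_labels, ps$channel_labels)
  new_pli_matrix(values, ps$band, ps$channel_labels, d[3])
}

new_pli_matrix <- function(values, band, channel_labels, n_epochs) {
  structure(
    list(
      values = values,
      band = band,
      channel_labels = channel_labels,
      n_epochs_averaged = n_epochs
    ),
    class = "pli_matrix"
  )
}

#' @export
print.pli_matrix <- function(x, ...) {
  cat(sprintf(
    "<pli_matrix> %s band (%g-%g Hz), %d channels, averaged over %d epochs\n",
    x$band$name, x$band$low, x$band$high, length(x$channel_labels),
    x$n_epochs_averaged
  ))
  cat(sprintf("global PLI (mean over pairs): %.4f\n", global_pli(x)))
  invisible(x)
}

#' Global PLI (mean over all channel pairs)
#'
#' The mean of the strictly upper-triangular entries of the connectivity
#' matrix — the whole-head synchronization summary.
#'
#' @param cm a `pli_matrix` (or a plain symmetric matrix).
#' @return scalar in `[0, 1]`.
#' @export
global_pli <- function(cm) {
  v <- if (inherits(cm, "pli_matrix")) cm$values else as.matrix(cm)
  mean(v[upper.tri(v)])
}

#' The eight posterior-involving electrode pairs of interest
#'
#' Three inter-hemispheric (F4-P3, P4-CP3, CP5-O2) and five intra-hemispheric
#' (C3-P3, C4-P8, F3-C5, F8-P8, CP3-O1) pairs.
#'
#' @return tibble with columns `chan_1`, `chan_2`, `region`.
#' @export
default_alpha_pairs <- function() {
  tibble::tibble(
    chan_1 = c("F4", "P4", "CP5", "C3", "C4", "F3", "F8", "CP3"),
    chan_2 = c("P3", "CP3", "O2", "P3", "P8", "C5", "P8", "O1"),
    region = c(rep("inter-hemispheric", 3), rep("intra-hemispheric", 5))
  )
}

#' Extract named electrode-pair PLI values
#'
#' @param cm a `pli_matrix`.
#' @param pairs two-column data frame (`chan_1`, `chan_2`) of channel labels;
#'   defaults to [default_alpha_pairs()].
#' @return tibble with `pair`, `chan_1`, `chan_2`, `pli` (input order
#'   preserved).
#' @export
extract_pairs <- function(cm, pairs = default_alpha_pairs()) {
  stopifnot(inherits(cm, "pli_matrix"))
  pairs <- tibble::as_tibble(pairs)
  missing <- setdiff(unique(c(pairs$chan_1, pairs$chan_2)), cm$channel_labels)
  if (length(missing)) {
    abort(sprintf("Unknown channel label(s): %s", paste(missing, collapse = ", ")))
  }
  dplyr::mutate(
    pairs,
    pair = paste0(.data$chan_1, "-", .data$chan_2),
    pli = purrr::map2_dbl(.data$chan_1, .data$chan_2, ~ cm$values[.x, .y]),
    .before = 1
  )
}

#' @export
tidy.pli_matrix <- function(x, ...) {
  labs <- x$channel_labels
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    band = x$band$name,
    chan_1 = labs[idx[, 1]],
    chan_2 = labs[idx[, 2]],
    pli = x$values[idx]
  )
}

#' Per-subject connectivity for a set of recordings
#'
#' Segments each recording into epochs (no filtering beyond the band filters
#' themselves; use [preprocess_recording()] upstream for the full chain) and
#' computes one connectivity matrix per band.
#'
#' @param recordings named list of [eeg_recording()] (or of [eeg_epochs()],
#'   used as-is).
#' @param bands tibble of bands as in [eeg_bands()] (any subset).
#' @param epoch_length epoch duration in seconds (ignored for epoch inputs).
#' @param edge_trim see [band_phase()].
#' @return tibble with columns `subject_id`, `band`, `matrix` (list column of
#'   `pli_matrix`), `global_pli`.
#' @export
cohort_connectivity <- function(recordings, bands = eeg_bands(),
                                epoch_length = 3, edge_trim = 0.1) {
  stopifnot(length(recordings) > 0, !is.null(names(recordings)))
  purrr::imap_dfr(recordings, function(rec, id) {
    es <- if (inherits(rec, "eeg_epochs")) rec else segment_epochs(rec, epoch_length)
    purrr::map_dfr(seq_len(nrow(bands)), function(b) {
      cm <- connectivity_matrix(es, bands[b, ], edge_trim)
      tibble::tibble(
        subject_id = id,
        band = bands$name[b],
        matrix = list(cm),
        global_pli = global_pli(cm)
      )
    })
  })
}
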