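# Preprocessing chain: re-reference -> band-pass -> notch -> downsample ->
# segment -> reject. All filters are zero-phase (forward-backward Butterworth)
# so downstream phase estimates are not biased by filter delay.

#' Drop channels by label
#'
#' @param rec an [eeg_recording()].
#' @param labels channel labels to remove (silently ignores absent ones).
#' @return an [eeg_recording()] without the named channels.
#' @export
drop_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- !(rec$channel_labels %in% labels)
  if (sum(keep) < 1) abort("Cannot drop all channels.")
  eeg_recording(rec$data[keep, , drop = FALSE], rec$channel_labels[keep],
                rec$sampling_rate, rec$annotations)
}

#' Re-reference to linked mastoids
#'
#' Subtracts the average of the left and right mastoid channels from every
#' channel, then drops the mastoids from the output. `A1`/`A2` are accepted
#' as synonyms for `M1`/`M2`.
#'
#' @param rec an [eeg_recording()].
#' @param left_label,right_label mastoid channel labels.
#' @return the re-referenced [eeg_recording()] (mastoids removed).
#' @export
rereference_mastoid <- function(rec, left_label = "M1", right_label = "M2") {
  stopifnot(inherits(rec, "eeg_recording"))
  find <- function(lab, alt) {
    hit <- match(lab, rec$channel_labels)
    if (is.na(hit)) hit <- match(alt, rec$channel_labels)
    if (is.na(hit)) abort(sprintf("Mastoid channel `%s` not found.", lab))
    hit
  }
  li <- find(left_label, "A1")
  ri <- find(right_label, "A2")
  ref <- 0.5 * (rec$data[li, ] + rec$data[ri, ])
  data <- sweep(rec$data, 2, ref, "-")
  keep <- setdiff(seq_len(nrow(data)), c(li, ri))
  eeg_recording(data[keep, , drop = FALSE], rec$channel_labels[keep],
                rec$sampling_rate, rec$annotations)
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth high-pass at `low` followed by a fourth-order
#' Butterworth low-pass at `high`, each applied forward-backward (zero
#' phase). The cascade is used instead of a single band-pass because a
#' band-pass with a very low normalized lower corner (0.1 Hz at 1000 Hz) is
#' numerically unstable in transfer-function form.
#'
#' @param rec an [eeg_recording()].
#' @param low,high corner frequencies in Hz.
#' @param order Butterworth order per section.
#' @return the filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort("Require 0 < low < high < sampling_rate / 2.")
  }
  x <- t(rec$data)
  x <- zp_butter(x, low / nyq, "high", order)
  x <- zp_butter(x, high / nyq, "low", order)
  eeg_recording(t(x), rec$channel_labels, rec$sampling_rate, rec$annotations)
}

#' Zero-phase band-stop (notch) filter
#'
#' Fourth-order Butterworth band-stop applied forward-backward; the default
#' 48-52 Hz band removes 50 Hz line noise.
#'
#' @inheritParams bandpass_filter
#' @export
notch_filter <- function(rec, low = 48, high = 52, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    abort("Require 0 < low < high < sampling_rate / 2.")
  }
  x <- zp_butter(t(rec$data), c(low, high) / nyq, "stop", order)
  eeg_recording(t(x), rec$channel_labels, rec$sampling_rate, rec$annotations)
}

#' Downsample by an integer factor
#'
#' Keeps every `rate/target`-th sample. No additional anti-alias filter is
#' applied: the chain runs this stage after the 30 Hz low-pass, which already
#' suppresses everything near the new Nyquist frequency.
#'
#' @param rec an [eeg_recording()].
#' @param target new sampling rate in Hz; must divide the current rate.
#' @return the downsampled [eeg_recording()].
#' @export
downsample <- function(rec, target = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- rec$sampling_rate / target
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    abort("`sampling_rate` must be an integer multiple of `target`.")
  }
  idx <- seq(1, ncol(rec$data), by = round(factor))
  eeg_recording(rec$data[, idx, drop = FALSE], rec$channel_labels, target,
                rec$annotations)
}

#' Segment a recording into fixed-length epochs
#'
#' Consecutive non-overlapping epochs; a trailing partial epoch is discarded.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_length epoch duration in seconds (default 3).
#' @return an [eeg_epochs()] object.
#' @export
segment_epochs <- function(rec, epoch_length = 3) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(epoch_length * rec$sampling_rate)
  n_epochs <- ncol(rec$data) %/% spe
  if (n_epochs < 1) abort("Recording is shorter than one epoch.")
  nch <- nrow(rec$data)
  arr <- array(NA_real_, c(n_epochs, nch, spe))
  for (e in seq_len(n_epochs)) {
    arr[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe)]
  }
  eeg_epochs(arr, epoch_length, rec$sampling_rate, rec$channel_labels)
}

#' Reject epochs by peak amplitude
#'
#' Drops every epoch whose maximum absolute amplitude on any channel exceeds
#' the threshold — a deterministic stand-in for manual/ICA artifact
#' screening.
#'
#' @param es an [eeg_epochs()] object.
#' @param amplitude_threshold rejection threshold in signal units (> 0).
#' @return the surviving [eeg_epochs()], with `kept_epoch_indices` updated.
#' @export
reject_epochs <- function(es, amplitude_threshold = 100) {
  stopifnot(inherits(es, "eeg_epochs"))
  check_number(amplitude_threshold, "amplitude_threshold", lower = 1e-12)
  peak <- apply(abs(es$epochs), 1, max)
  keep <- peak <= amplitude_threshold
  if (!any(keep)) abort("All epochs exceed the amplitude threshold.")
  eeg_epochs(es$epochs[keep, , , drop = FALSE], es$epoch_length,
             es$sampling_rate, es$channel_labels,
             kept_epoch_indices = es$kept_epoch_indices[keep])
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: drop EOG channels (HEO/VEO) if present, re-reference to
#' linked mastoids (skipped with a log note when no mastoid channels exist),
#' band-pass, notch, downsample, segment into epochs, reject by amplitude.
#'
#' @param rec an [eeg_recording()].
#' @param bandpass length-2 numeric, band-pass corners in Hz.
#' @param notch length-2 numeric, band-stop corners in Hz (`NULL` skips).
#' @param target_rate downsampling target in Hz (`NULL` skips).
#' @param epoch_length epoch duration in seconds.
#' @param amplitude_threshold epoch-rejection threshold (`NULL` skips).
#' @return list with `epochs` (an [eeg_epochs()]) and `log` (character
#'   vector, one entry per stage with its parameters).
#' @export
preprocess_recording <- function(rec,
                                 bandpass = c(0.1, 30),
                                 notch = c(48, 52),
                                 target_rate = 500,
                                 epoch_length = 3,
                                 amplitude_threshold = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  eog <- intersect(c("HEO", "VEO"), rec$channel_labels)
  if (length(eog)) {
    rec <- drop_channels(rec, eog)
    note("drop_eog: removed %s", paste(eog, collapse = ", "))
  }
  if (any(c("M1", "A1") %in% rec$channel_labels) &&
      any(c("M2", "A2") %in% rec$channel_labels)) {
    rec <- rereference_mastoid(rec)
    note("rereference: linked mastoids, mastoid channels dropped")
  } else {
    note("rereference: skipped (no mastoid channels)")
  }
  rec <- bandpass_filter(rec, bandpass[1], bandpass[2])
  note("bandpass: %g-%g Hz zero-phase Butterworth", bandpass[1], bandpass[2])
  if (!is.null(notch)) {
    rec <- notch_filter(rec, notch[1], notch[2])
    note("notch: %g-%g Hz zero-phase band-stop", notch[1], notch[2])
  }
  if (!is.null(target_rate) && target_rate < rec$sampling_rate) {
    rec <- downsample(rec, target_rate)
    note("downsample: to %g Hz", target_rate)
  }
  es <- segment_epochs(rec, epoch_length)
  note("segment: %d epochs of %g s", dim(es$epochs)[1], epoch_length)
  if (!is.null(amplitude_threshold)) {
    n0 <- dim(es$epochs)[1]
    es <- reject_epochs(es, amplitude_threshold)
    note("reject: threshold %g, kept %d / %d epochs",
         amplitude_threshold, dim(es$epochs)[1], n0)
  }
  list(epochs = es, log = log)
}
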