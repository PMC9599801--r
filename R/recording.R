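# EEG recording and epoch containers.

#' Construct an EEG recording
#'
#' A recording is a channels-by-samples real matrix with channel labels and a
#' sampling rate; the raw unit of analysis.
#'
#' @param data numeric matrix, channels x samples.
#' @param channel_labels character vector, one label per row of `data`.
#' @param sampling_rate sampling rate in Hz.
#' @param annotations optional tibble of (start, end, label) annotations in
#'   seconds.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate, annotations = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels)) {
    abort("`channel_labels` must have one entry per row of `data`.")
  }
  if (anyDuplicated(channel_labels)) abort("`channel_labels` must be unique.")
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  if (!all(is.finite(data))) abort("All samples must be finite.")
  structure(
    list(
      data = data,
      channel_labels = as.character(channel_labels),
      sampling_rate = sampling_rate,
      annotations = annotations
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$sampling_rate, ncol(x$data) / x$sampling_rate
  ))
  cat("channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "...", "\n")
  invisible(x)
}

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    time = rep((seq_len(ncol(x$data)) - 1) / x$sampling_rate,
               times = nrow(x$data)),
    channel = rep(x$channel_labels, each = ncol(x$data)),
    value = as.numeric(t(x$data))
  )
}

#' Extended 10-20 montage labels
#'
#' Returns scalp channel labels from the international extended 10-20 system.
#' The full set has 62 channels (a 64-electrode cap minus the two mastoids);
#' smaller counts return standard symmetric subsets suited to reduced
#' simulations.
#'
#' @param n_channels number of labels (2, 4, 8, 16 or 62; other values take
#'   the first `n_channels` of the full list).
#' @return character vector of channel labels.
#' @export
montage_10_20 <- function(n_channels = 62) {
  full <- c(
    "FP1", "FPZ", "FP2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "CB1", "O1", "OZ", "O2", "CB2"
  )
  subsets <- list(
    `2` = c("C3", "C4"),
    `4` = c("F3", "F4", "P3", "P4"),
    `8` = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
    `16` = c("FP1", "FP2", "F3", "F4", "F7", "F8", "C3", "C4",
             "T7", "T8", "P3", "P4", "P7", "P8", "O1", "O2")
  )
  key <- as.character(n_channels)
  if (key %in% names(subsets)) return(subsets[[key]])
  if (n_channels == 62) return(full)
  if (n_channels < 1 || n_channels > 62) abort("`n_channels` must be in 1..62.")
  full[seq_len(n_channels)]
}

# Channels in the central/parietal/parieto-occipital strip where alpha
# coupling is emphasised by default (C*, CP*, P*, PO* but not CB*).
is_centro_parietal <- function(labels) {
  grepl("^(C|CP|P|PO)([0-9]+|Z)$", toupper(labels))
}

#' Write / read a recording as a plain-text fixture
#'
#' The native exchange format: a tab-separated samples-by-channels table whose
#' header row holds the channel labels, plus a JSON sidecar
#' (`<path>.meta.json`) with the sampling rate.
#'
#' @param rec an [eeg_recording()].
#' @param path file path for the matrix (sidecar written next to it).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- tibble::as_tibble(t(rec$data), .name_repair = "minimal")
  names(df) <- rec$channel_labels
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_recording
#' @param sampling_rate overrides the sidecar value when supplied.
#' @export
read_recording <- function(path, sampling_rate = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(sampling_rate)) {
    meta_path <- paste0(path, ".meta.json")
    if (!file.exists(meta_path)) {
      abort("No `sampling_rate` given and no .meta.json sidecar found.")
    }
    sampling_rate <- as.numeric(jsonlite::read_json(meta_path)$sampling_rate)
  }
  eeg_recording(t(as.matrix(df)), names(df), sampling_rate)
}

#' Construct an epoch set
#'
#' Fixed-length segments cut from one recording, stored as an
#' epoch x channel x sample array.
#'
#' @param epochs numeric array with dim (n_epochs, n_channels, n_samples).
#' @param epoch_length epoch duration in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels channel labels.
#' @param kept_epoch_indices indices of the epochs in the original segmented
#'   recording (updated by [reject_epochs()]).
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, epoch_length, sampling_rate, channel_labels,
                       kept_epoch_indices = seq_len(dim(epochs)[1])) {
  stopifnot(length(dim(epochs)) == 3)
  if (dim(epochs)[2] != length(channel_labels)) {
    abort("Channel count must match `channel_labels`.")
  }
  if (dim(epochs)[3] != round(epoch_length * sampling_rate)) {
    abort("Every epoch must have exactly epoch_length x sampling_rate samples.")
  }
  structure(
    list(
      epochs = epochs,
      epoch_length = epoch_length,
      sampling_rate = sampling_rate,
      channel_labels = as.character(channel_labels),
      kept_epoch_indices = kept_epoch_indices
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<eeg_epochs> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
    d[1], d[2], d[3], x$epoch_length, x$sampling_rate
  ))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
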