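# Synthetic two-cohort EEG with known phase-coupling ground truth.

#' Specification of one synthetic EEG recording
#'
#' Each channel is a weighted sum of shared band-limited oscillators plus
#' independent background noise:
#' `x_c(t) = signal_scale * sum_b kappa_b * m_c * Re[a_b(t) exp(-i phi_c)] + noise_sd * e_c(t)`
#' where `a_b` is the unit-variance analytic signal of a band-limited Gaussian
#' source, `phi_c` the per-channel phase lag (a constant instantaneous phase
#' offset, so the noiseless pairwise PLI between channels with different lags
#' is exactly 1), `m_c` a regional gain and `e_c` unit-variance white or pink
#' noise. `kappa_b` is therefore the source-to-noise amplitude ratio per band.
#'
#' @param n_channels number of scalp channels (default 62).
#' @param sampling_rate sampling rate in Hz (default 1000).
#' @param duration recording length in seconds (default 300, i.e. five
#'   minutes of eyes-closed rest).
#' @param channel_labels montage labels; defaults to
#'   [montage_10_20()]`(n_channels)`.
#' @param oscillator_bands tibble with columns `name`, `center` (Hz),
#'   `bandwidth` (Hz) and `kappa` (coupling strength, >= 0). Defaults to one
#'   oscillator per classical band with alpha the strongest.
#' @param channel_phase_lags radians per channel; default evenly spaced on
#'   `[0, 0.8*pi]` so every pair has a distinct non-zero lag.
#' @param regional_gain multiplier applied to the shared source on
#'   central/parietal/parieto-occipital channels (C*, CP*, P*, PO*),
#'   emphasising posterior alpha coupling; 1 disables.
#' @param signal_scale amplitude of a kappa = 1 source, in the same
#'   microvolt-like units as `noise_sd`. With the defaults
#'   (`signal_scale == noise_sd == 10`) `kappa` reads directly as the
#'   source-to-noise amplitude ratio.
#' @param noise_sd background-noise amplitude (0 gives a noiseless
#'   recording).
#' @param noise_color `"pink"` (1/f, the resting-EEG-like default) or
#'   `"white"`.
#' @param include_aux append mastoid (M1, M2) and EOG (HEO, VEO) channels so
#'   the full preprocessing chain can be exercised.
#' @param artifact_rate expected number of high-amplitude artifact spikes per
#'   minute (0 disables); used to test epoch rejection.
#' @param artifact_amplitude spike amplitude in the same units as `noise_sd`.
#' @return a `recording_spec` list.
#' @export
recording_spec <- function(n_channels = 62,
                           sampling_rate = 1000,
                           duration = 300,
                           channel_labels = montage_10_20(n_channels),
                           oscillator_bands = default_oscillators(),
                           channel_phase_lags = NULL,
                           regional_gain = 1.3,
                           signal_scale = 10,
                           noise_sd = 10,
                           noise_color = c("pink", "white"),
                           include_aux = FALSE,
                           artifact_rate = 0,
                           artifact_amplitude = 200) {
  noise_color <- match.arg(noise_color)
  if (n_channels < 2) abort("At least 2 channels are required.")
  if (length(channel_labels) != n_channels || anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique and match `n_channels`.")
  }
  check_number(sampling_rate, "sampling_rate", lower = 1e-9)
  check_number(duration, "duration", lower = 1e-9)
  n <- duration * sampling_rate
  if (abs(n - round(n)) > 1e-8) {
    abort("duration x sampling_rate must be a whole number of samples.")
  }
  if (is.null(channel_phase_lags)) {
    channel_phase_lags <- seq(0, 0.8 * pi, length.out = n_channels)
  }
  if (length(channel_phase_lags) != n_channels) {
    abort("`channel_phase_lags` must have one entry per channel.")
  }
  stopifnot(is.data.frame(oscillator_bands),
            all(c("name", "center", "bandwidth", "kappa") %in% names(oscillator_bands)))
  if (any(oscillator_bands$kappa < 0)) abort("Coupling strengths must be >= 0.")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(signal_scale, "signal_scale", lower = 0)
  check_number(regional_gain, "regional_gain", lower = 0)
  structure(
    list(
      n_channels = as.integer(n_channels),
      sampling_rate = sampling_rate,
      duration = duration,
      channel_labels = as.character(channel_labels),
      oscillator_bands = tibble::as_tibble(oscillator_bands),
      channel_phase_lags = channel_phase_lags,
      regional_gain = regional_gain,
      signal_scale = signal_scale,
      noise_sd = noise_sd,
      noise_color = noise_color,
      include_aux = include_aux,
      artifact_rate = artifact_rate,
      artifact_amplitude = artifact_amplitude
    ),
    class = "recording_spec"
  )
}

#' Default shared oscillators, one per classical EEG band
#'
#' Alpha is the strongest source (resting eyes-closed EEG), beta the weakest.
#'
#' @return tibble with columns name, center, bandwidth, kappa.
#' @export
default_oscillators <- function() {
  tibble::tibble(
    name = c("delta", "theta", "alpha", "beta"),
    center = c(2.5, 6, 10.5, 21.5),
    bandwidth = c(3, 4, 5, 17),
    kappa = c(0.6, 0.6, 1.0, 0.4)
  )
}

# 1/f-amplitude Gaussian noise, unit variance, one column per series.
pink_noise <- function(n, n_series) {
  white <- matrix(rnorm(n * n_series), n, n_series)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)  # two-sided frequency bin index
  f[1] <- 1            # keep DC finite
  scale <- 1 / sqrt(f)
  x <- Re(mvfft(mvfft(white) * scale, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, sd), "/")
}

#' Generate one synthetic EEG recording
#'
#' Deterministic given `(spec, seed)`.
#'
#' @param spec a [recording_spec()].
#' @param seed integer seed.
#' @return an [eeg_recording()].
#' @export
generate_recording <- function(spec, seed) {
  stopifnot(inherits(spec, "recording_spec"))
  seed <- as.integer(seed)
  n <- round(spec$duration * spec$sampling_rate)
  fs <- spec$sampling_rate
  nch <- spec$n_channels

  withr::with_seed(seed, {
    gain <- ifelse(is_centro_parietal(spec$channel_labels), spec$regional_gain, 1)
    coupled <- matrix(0, n, nch)
    for (b in seq_len(nrow(spec$oscillator_bands))) {
      band <- spec$oscillator_bands[b, ]
      if (band$kappa == 0) next
      low <- max(band$center - band$bandwidth / 2, 1e-3)
      high <- min(band$center + band$bandwidth / 2, fs / 2 * 0.99)
      src <- zp_butter(rnorm(n), c(low, high) / (fs / 2), "pass")
      src <- src / sd(src)
      a <- analytic_signal(src)
      for (ch in seq_len(nch)) {
        coupled[, ch] <- coupled[, ch] +
          band$kappa * gain[ch] * Re(a * exp(-1i * spec$channel_phase_lags[ch]))
      }
    }
    x <- spec$signal_scale * coupled
    if (spec$noise_sd > 0) {
      noise <- if (spec$noise_color == "pink") {
        pink_noise(n, nch)
      } else {
        matrix(rnorm(n * nch), n, nch)
      }
      x <- x + spec$noise_sd * noise
    }

    if (spec$artifact_rate > 0) {
      n_art <- rpois(1, spec$artifact_rate * spec$duration / 60)
      if (n_art > 0) {
        width <- max(1L, round(0.2 * fs))
        for (k in seq_len(n_art)) {
          ch <- sample.int(nch, 1)
          start <- sample.int(max(1L, n - width), 1)
          x[start:(start + width - 1), ch] <-
            x[start:(start + width - 1), ch] + spec$artifact_amplitude
        }
      }
    }

    labels <- spec$channel_labels
    if (spec$include_aux) {
      aux <- 0.5 * max(spec$noise_sd, spec$signal_scale) * matrix(rnorm(n * 4), n, 4)
      x <- cbind(x, aux)
      labels <- c(labels, "M1", "M2", "HEO", "VEO")
    }
    eeg_recording(t(x), labels, fs)
  })
}

#' Specification of a synthetic two-group cohort
#'
#' Emulates a patient (`MCI`) versus control (`NC`) study: per-subject alpha
#' coupling is log-normally jittered around the spec's alpha `kappa`,
#' multiplied by `group_effect` in the patient group, and the MoCA cognitive
#' score is a linear function of that realized coupling plus Gaussian
#' residual, so the implied coupling-MoCA Pearson correlation is known in
#' closed form (`slope * sd(coupling) / sd(MoCA)`).
#'
#' @param n_per_group subjects per group (default 30).
#' @param group_effect multiplicative reduction of alpha coupling in the
#'   patient group, in (0, 1]; the default 0.8 is calibrated so the default
#'   reduced cohort detects the group difference with high power.
#' @param coupling_sd_log log-scale SD of the per-subject alpha coupling
#'   jitter.
#' @param moca_model named list with entries `MCI` and `NC`, each
#'   `c(intercept, slope, resid_sd)` for
#'   `MoCA = intercept + slope * coupling + N(0, resid_sd)`.
#' @param covariates named list of per-group distributions for age,
#'   education (years), sex (probability of male) and diabetes duration;
#'   defaults match a typical matched elderly T2DM cohort.
#' @param recording a [recording_spec()] for the per-subject EEG.
#' @param seed master seed; per-subject recording seeds are drawn from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 30,
                        group_effect = 0.8,
                        coupling_sd_log = 0.15,
                        moca_model = default_moca_model(),
                        covariates = default_covariates(),
                        recording = recording_spec(),
                        seed = 1L) {
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")
  if (group_effect <= 0 || group_effect > 1) abort("`group_effect` must be in (0, 1].")
  check_number(coupling_sd_log, "coupling_sd_log", lower = 0)
  for (g in c("MCI", "NC")) {
    if (moca_model[[g]][3] <= 0) abort("MoCA residual sd must be > 0.")
  }
  for (v in c("age", "education", "duration")) {
    if (any(vapply(covariates[[v]], function(p) unname(p["sd"]), 0) <= 0)) {
      abort(sprintf("Covariate `%s` must have sd > 0 in both groups.", v))
    }
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      group_effect = group_effect,
      coupling_sd_log = coupling_sd_log,
      moca_model = moca_model,
      covariates = covariates,
      recording = recording,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_moca_model <- function() {
  # Slopes/residuals chosen so the implied coupling-MoCA correlation is
  # moderate in the patient group (~0.48) and weak in controls (~0.26), with
  # group MoCA means/SDs near 22.1 +/- 2.2 and 28.1 +/- 1.4.
  list(
    MCI = c(intercept = 14.9, slope = 9.0, resid_sd = 1.96),
    NC = c(intercept = 25.6, slope = 2.5, resid_sd = 1.36)
  )
}

#' @rdname cohort_spec
#' @export
default_covariates <- function() {
  list(
    age = list(MCI = c(mean = 67.17, sd = 4.12), NC = c(mean = 67.73, sd = 4.40)),
    education = list(MCI = c(mean = 10.63, sd = 3.75), NC = c(mean = 10.23, sd = 3.23)),
    sex_p_male = c(MCI = 13 / 30, NC = 16 / 30),
    duration = list(MCI = c(mean = 14.23, sd = 7.80), NC = c(mean = 15.43, sd = 8.34)),
    mci_duration = c(mean = 3.33, sd = 1.86)
  )
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param make_recordings generate the per-subject EEG (set `FALSE` to obtain
#'   only the clinical table with its latent coupling ground truth, e.g. for
#'   cheap Monte-Carlo studies of the MoCA model).
#' @return a list with `cohort` (tibble: subject_id, group, sex, age,
#'   education_years, moca, t2dm_duration_years, mci_duration_years,
#'   true_alpha_coupling, recording_seed) and `recordings` (named list of
#'   [eeg_recording()], or `NULL`).
#' @export
generate_cohort <- function(spec, make_recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  npg <- spec$n_per_group
  n <- 2L * npg
  group <- rep(c("MCI", "NC"), each = npg)
  cv <- spec$covariates
  mm <- spec$moca_model
  base_kappa <- spec$recording$oscillator_bands$kappa[
    spec$recording$oscillator_bands$name == "alpha"
  ]
  if (length(base_kappa) != 1) abort("The recording spec must contain exactly one alpha oscillator.")

  tbl <- withr::with_seed(spec$seed, {
    eff <- ifelse(group == "MCI", spec$group_effect, 1)
    kappa <- base_kappa * eff * exp(rnorm(n, 0, spec$coupling_sd_log))
    draw2 <- function(param) {
      out <- numeric(n)
      for (g in c("MCI", "NC")) {
        idx <- group == g
        out[idx] <- rnorm(sum(idx), param[[g]]["mean"], param[[g]]["sd"])
      }
      out
    }
    moca <- numeric(n)
    for (g in c("MCI", "NC")) {
      idx <- group == g
      moca[idx] <- mm[[g]]["intercept"] + mm[[g]]["slope"] * kappa[idx] +
        rnorm(sum(idx), 0, mm[[g]]["resid_sd"])
    }
    tibble::tibble(
      subject_id = sprintf("sub%03d", seq_len(n)),
      group = group,
      sex = ifelse(rbinom(n, 1, cv$sex_p_male[group]) == 1, "M", "F"),
      age = round(draw2(cv$age), 1),
      education_years = pmax(0, round(draw2(cv$education))),
      moca = pmin(30, pmax(0, moca)),
      t2dm_duration_years = pmax(0.5, round(draw2(cv$duration), 1)),
      mci_duration_years = ifelse(
        group == "MCI",
        pmax(0.1, round(rnorm(n, cv$mci_duration["mean"], cv$mci_duration["sd"]), 1)),
        NA_real_
      ),
      true_alpha_coupling = kappa,
      recording_seed = derive_seeds(spec$seed + 1L, n)
    )
  })

  recordings <- NULL
  if (make_recordings) {
    recordings <- purrr::map2(tbl$true_alpha_coupling, tbl$recording_seed, function(k, s) {
      rs <- spec$recording
      rs$oscillator_bands$kappa[rs$oscillator_bands$name == "alpha"] <- k
      generate_recording(rs, s)
    })
    names(recordings) <- tbl$subject_id
  }
  list(cohort = tbl, recordings = recordings)
}
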