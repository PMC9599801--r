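# Preprocessing chain: re-referencing, zero-phase filters, downsampling,
# epoching, amplitude rejection.

test_that("mastoid re-referencing subtracts the mastoid average and drops them", {
  withr::with_seed(1, {
    x <- matrix(rnorm(6 * 100), 6, 100)
  })
  rec <- matrix_recording(x, labels = c("F3", "F4", "P3", "P4", "M1", "M2"))
  out <- rereference_mastoid(rec)
  ref <- 0.5 * (x[5, ] + x[6, ])
  expect_identical(out$channel_labels, c("F3", "F4", "P3", "P4"))
  expect_equal(out$data, sweep(x[1:4, ], 2, ref), ignore_attr = TRUE)

  # zero mastoids leave the data unchanged
  x0 <- x; x0[5:6, ] <- 0
  out0 <- rereference_mastoid(matrix_recording(x0, labels = rec$channel_labels))
  expect_equal(out0$data, x0[1:4, ], ignore_attr = TRUE)

  # channels identical to the mastoids become zero
  x1 <- matrix(rep(x[5, ], 6), 6, byrow = TRUE)
  out1 <- rereference_mastoid(matrix_recording(x1, labels = rec$channel_labels))
  expect_true(all(out1$data == 0))
})

test_that("A1/A2 are accepted as mastoid synonyms and absences are named", {
  x <- matrix(0, 3, 50)
  rec <- matrix_recording(x, labels = c("F3", "A1", "A2"))
  expect_identical(rereference_mastoid(rec)$channel_labels, "F3")
  expect_error(rereference_mastoid(matrix_recording(x)), "M1")
})

test_that("band-pass keeps the passband and crushes the stopband", {
  # the 0.1 Hz high-pass has a ~10 s impulse response, so measure on a
  # window long enough that boundary effects cannot reach the middle
  in10 <- sine_recording(10, fs = 1000, duration = 120)
  out10 <- bandpass_filter(in10)
  ratio <- mid_rms(out10$data[1, ], frac = 0.5) / mid_rms(in10$data[1, ], frac = 0.5)
  expect_true(ratio > 0.95 && ratio < 1.05)

  in80 <- sine_recording(80, fs = 1000, duration = 120)
  out80 <- bandpass_filter(in80)
  atten_db <- 20 * log10(
    mid_rms(in80$data[1, ], frac = 0.5) / mid_rms(out80$data[1, ], frac = 0.5)
  )
  expect_gt(atten_db, 40)

  zero <- matrix_recording(matrix(0, 1, 5000), fs = 1000)
  expect_true(all(bandpass_filter(zero)$data == 0))
  expect_error(bandpass_filter(in10, low = 30, high = 10), "low < high")
  expect_error(bandpass_filter(in10, low = 0.1, high = 600), "low < high")
})

test_that("notch removes 50 Hz line noise but keeps 10 Hz", {
  in50 <- sine_recording(50, fs = 1000, duration = 20)
  atten_db <- 20 * log10(
    mid_rms(in50$data[1, ]) / mid_rms(notch_filter(in50)$data[1, ])
  )
  expect_gt(atten_db, 30)

  in10 <- sine_recording(10, fs = 1000, duration = 20)
  ratio <- mid_rms(notch_filter(in10)$data[1, ]) / mid_rms(in10$data[1, ])
  expect_true(ratio > 0.95 && ratio < 1.05)

  zero <- matrix_recording(matrix(0, 1, 5000), fs = 1000)
  expect_true(all(notch_filter(zero)$data == 0))
})

test_that("zero-phase filtering preserves the symmetry of a symmetric pulse", {
  # corners chosen so the filter response is much shorter than the window;
  # only then does finite-window truncation not break the symmetry
  n <- 20001
  pulse <- exp(-((seq_len(n) - (n + 1) / 2)^2) / (2 * 100^2))
  rec <- matrix_recording(matrix(pulse, 1), fs = 1000)
  y <- bandpass_filter(rec, 1, 30)$data[1, ]
  expect_lt(max(abs(y - rev(y))), 1e-6 * max(abs(y)))
  yn <- notch_filter(rec)$data[1, ]
  expect_lt(max(abs(yn - rev(yn))), 1e-6 * max(abs(yn)))
})

test_that("the biquad cascade agrees with an independent zero-phase filter", {
  skip_if_not_installed("signal")
  withr::with_seed(11, x <- rnorm(6000))
  # well-conditioned designs where the transfer-function form is reliable
  mine_bp <- eegpli:::zp_butter(x, c(8, 13) / 250, "pass")
  ref_bp <- signal::filtfilt(signal::butter(4, c(8, 13) / 250, type = "pass"), x)
  mid <- 1000:5000
  expect_lt(max(abs(mine_bp[mid] - ref_bp[mid])), 1e-4 * sd(ref_bp[mid]))

  mine_lp <- eegpli:::zp_butter(x, 30 / 250, "low")
  ref_lp <- signal::filtfilt(signal::butter(4, 30 / 250, type = "low"), x)
  expect_lt(max(abs(mine_lp[mid] - ref_lp[mid])), 1e-4 * sd(ref_lp[mid]))
})

test_that("downsampling keeps every k-th sample and the spectral peak", {
  rec <- sine_recording(10, fs = 1000, duration = 30)
  out <- downsample(rec, 500)
  expect_identical(ncol(out$data), 15000L)
  expect_identical(out$sampling_rate, 500)
  spec <- Mod(fft(out$data[1, ]))[1:7500]
  freqs <- (seq_len(7500) - 1) * 500 / 15000
  expect_equal(freqs[which.max(spec)], 10, tolerance = 0.05)
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("epoching counts and reconstruction are exact", {
  withr::with_seed(2, x <- matrix(rnorm(3 * 150000), 3))
  rec <- matrix_recording(x, fs = 500)
  es <- segment_epochs(rec, 3)
  expect_identical(dim(es$epochs), c(100L, 3L, 1500L))

  # concatenating the epochs reproduces the (truncated) recording exactly
  recon <- do.call(cbind, lapply(seq_len(dim(es$epochs)[1]), function(e) {
    matrix(es$epochs[e, , ], nrow = 3)
  }))
  expect_identical(recon, x[, seq_len(ncol(recon))])

  short <- matrix_recording(matrix(rnorm(2 * 448), 2), fs = 128)
  expect_identical(dim(segment_epochs(short, 3)$epochs)[1], 1L)  # 3.5 s -> 1
  expect_error(
    segment_epochs(matrix_recording(matrix(0, 2, 256), fs = 128), 3),
    "shorter than one epoch"
  )
})

test_that("amplitude rejection drops exactly the contaminated epochs", {
  withr::with_seed(3, x <- matrix(rnorm(2 * 128 * 30), 2))
  x[1, 128 * 3 * 4 + 10] <- 1000  # spike inside epoch 5
  es <- segment_epochs(matrix_recording(x, fs = 128), 3)

  kept <- reject_epochs(es, 100)
  expect_identical(setdiff(seq_len(10), kept$kept_epoch_indices), 5L)
  expect_identical(dim(kept$epochs)[1], 9L)

  all_kept <- reject_epochs(es, 1e9)
  expect_identical(dim(all_kept$epochs)[1], 10L)

  expect_error(reject_epochs(es, 1e-6), "All epochs")
  expect_error(reject_epochs(es, 0), "amplitude_threshold")
})

test_that("the full chain drops EOG/mastoids, filters, downsamples, epochs", {
  spec <- quick_spec(n_channels = 4, sampling_rate = 500, duration = 18,
                     include_aux = TRUE)
  rec <- generate_recording(spec, 4)
  pp <- preprocess_recording(rec, target_rate = 250, notch = c(48, 52),
                             epoch_length = 3, amplitude_threshold = 1e6)
  expect_identical(pp$epochs$channel_labels, spec$channel_labels)
  expect_identical(pp$epochs$sampling_rate, 250)
  expect_identical(dim(pp$epochs$epochs), c(6L, 4L, 750L))
  expect_true(any(grepl("rereference: linked mastoids", pp$log)))
  expect_true(any(grepl("drop_eog", pp$log)))
})
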