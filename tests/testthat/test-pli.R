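# Phase extraction and the PLI estimator.

test_that("instantaneous phase of a pure alpha tone advances at 2*pi*f", {
  rec <- sine_recording(10, fs = 500, duration = 12)
  es <- segment_epochs(rec, 3)
  ps <- band_phase(es, "alpha", edge_trim = 0.1)
  ph <- ps$phases[, 1, 2]  # one channel, one epoch
  unwrapped <- cumsum(c(ph[1], wrap_phase <- eegpli:::wrap_phase(diff(ph))))
  fit <- stats::lm(unwrapped ~ seq_along(unwrapped))
  slope_hz <- unname(stats::coef(fit)[2]) * 500 / (2 * pi)
  expect_equal(slope_hz, 10, tolerance = 0.01)
})

test_that("a quadrature pair shows a constant pi/2 phase difference", {
  t <- (0:(500 * 12 - 1)) / 500
  x <- cos(2 * pi * 10 * t)
  y <- cos(2 * pi * 10 * t - pi / 2)
  es <- segment_epochs(matrix_recording(rbind(x, y), fs = 500), 3)
  ps <- band_phase(es, "alpha")
  d <- eegpli:::wrap_phase(ps$phases[, 1, ] - ps$phases[, 2, ])
  expect_lt(max(abs(d - pi / 2)), 0.05)
})

test_that("zero signal has undefined phase and errors", {
  es <- segment_epochs(matrix_recording(matrix(0, 2, 500 * 6), fs = 500), 3)
  expect_error(band_phase(es, "alpha"), "undefined")
})

test_that("bands outside Nyquist and bad trims are rejected", {
  es <- segment_epochs(sine_recording(5, fs = 50, duration = 6, n_channels = 2), 3)
  expect_error(band_phase(es, "beta"), "Nyquist")
  expect_error(band_phase(es, "alpha", edge_trim = 0.5), "edge_trim")
})

test_that("pli_pair matches its definition on canonical cases", {
  expect_identical(pli_pair(rep(0.3, 100), rep(0.3, 100)), 0)  # sign(0) = 0
  expect_identical(pli_pair(rep(pi / 2, 50), rep(0, 50)), 1)
  # wrapped difference of exactly pi lies in (-pi, pi] -> sign +1
  expect_identical(pli_pair(rep(pi, 50), rep(0, 50)), 1)
  # mixed leads and lags cancel
  expect_equal(pli_pair(c(0.1, -0.1, 0.2, -0.2), c(0, 0, 0, 0)), 0)
  expect_error(pli_pair(numeric(0), numeric(0)), "non-empty")
  expect_error(pli_pair(1:3, 1:4), "equal length")
})

test_that("independent uniform phases give the finite-sample PLI floor", {
  # E|mean of N random signs| ~= sqrt(2 / (pi N)); light Monte-Carlo here,
  # the full-depth version runs in the acceptance suite.
  n <- 1500
  reps <- 800
  vals <- withr::with_seed(42, {
    vapply(seq_len(reps), function(i) {
      pli_pair(stats::runif(n, -pi, pi), stats::runif(n, -pi, pi))
    }, 0)
  })
  expected <- sqrt(2 / (pi * n))
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - expected), 4 * se)
})

test_that("the C++ all-pairs kernel agrees with the R estimator", {
  withr::with_seed(7, ph <- matrix(stats::runif(200 * 5, -pi, pi), 200, 5))
  m <- eegpli:::cpp_pli_matrix(ph)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j], pli_pair(ph[, i], ph[, j]))
  }
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
})

test_that("connectivity matrices satisfy their invariants", {
  spec <- quick_spec(n_channels = 4, duration = 24)
  es <- segment_epochs(generate_recording(spec, 5), 3)
  for (agg in c("epochs", "pooled")) {
    cm <- connectivity_matrix(es, "alpha", aggregate = agg)
    expect_identical(cm$values, t(cm$values))
    expect_true(all(diag(cm$values) == 0))
    expect_true(all(cm$values >= 0 & cm$values <= 1))
  }
  expect_error(
    connectivity_matrix(
      segment_epochs(sine_recording(10, fs = 128, duration = 6), 3)
    ),
    "2 channels"
  )
})

test_that("identical channels give a zero connectivity matrix", {
  rec <- sine_recording(10, fs = 128, duration = 12, n_channels = 3)
  cm <- connectivity_matrix(segment_epochs(rec, 3), "alpha")
  expect_true(all(cm$values == 0))
})

test_that("channel relabeling permutes the matrix and preserves global PLI", {
  spec <- quick_spec(n_channels = 5, duration = 15)
  es <- segment_epochs(generate_recording(spec, 6), 3)
  cm <- connectivity_matrix(es, "alpha")

  perm <- c(3, 1, 5, 2, 4)
  es_p <- eeg_epochs(es$epochs[, perm, , drop = FALSE], es$epoch_length,
                     es$sampling_rate, es$channel_labels[perm])
  cm_p <- connectivity_matrix(es_p, "alpha")
  expect_equal(cm_p$values, cm$values[perm, perm], tolerance = 1e-12)
  expect_equal(global_pli(cm_p), global_pli(cm), tolerance = 1e-12)
})

test_that("global PLI equals brute-force enumeration over all pairs", {
  v <- random_pli_values(62, seed = 21)
  cm <- fixture_pli_matrix(v, labels = montage_10_20(62))
  total <- 0
  count <- 0
  for (i in 1:61) for (j in (i + 1):62) {
    total <- total + v[i, j]
    count <- count + 1
  }
  expect_identical(count, choose(62, 2))
  expect_equal(global_pli(cm), total / count, tolerance = 1e-12)

  zero <- fixture_pli_matrix(matrix(0, 4, 4))
  expect_identical(global_pli(zero), 0)
  const <- matrix(0.37, 4, 4); diag(const) <- 0
  expect_equal(global_pli(fixture_pli_matrix(const)), 0.37)
})

test_that("named pair extraction retrieves planted values in order", {
  v <- random_pli_values(62, seed = 22)
  cm <- fixture_pli_matrix(v, labels = montage_10_20(62))
  out <- extract_pairs(cm)
  expect_identical(out$pair, paste0(out$chan_1, "-", out$chan_2))
  expect_identical(nrow(out), 8L)
  for (k in seq_len(8)) {
    expect_identical(out$pli[k], cm$values[out$chan_1[k], out$chan_2[k]])
    expect_identical(out$pli[k], cm$values[out$chan_2[k], out$chan_1[k]])  # symmetry
  }
  same <- extract_pairs(cm, tibble::tibble(chan_1 = "CZ", chan_2 = "CZ"))
  expect_identical(same$pli, 0)
  expect_error(
    extract_pairs(cm, tibble::tibble(chan_1 = "NOPE", chan_2 = "CZ")),
    "NOPE"
  )
})

test_that("volume-conducted (zero-lag) mixing stays at the floor, lag does not", {
  floor_vals <- lag_vals <- zero_lag_vals <- numeric(8)
  for (s in 1:8) {
    base <- quick_spec(n_channels = 2, duration = 24)
    zl <- base; zl$channel_phase_lags <- c(0.4, 0.4)
    ind <- base; ind$oscillator_bands$kappa <- 0
    lg <- base; lg$channel_phase_lags <- c(0, pi / 2); lg$noise_sd <- 1
    pli_of <- function(sp, seed) {
      global_pli(connectivity_matrix(
        segment_epochs(generate_recording(sp, seed), 3), "alpha"
      ))
    }
    zero_lag_vals[s] <- pli_of(zl, 100 + s)
    floor_vals[s] <- pli_of(ind, 200 + s)
    lag_vals[s] <- pli_of(lg, 300 + s)
  }
  expect_lt(abs(mean(zero_lag_vals) - mean(floor_vals)), 0.08)
  expect_lt(mean(zero_lag_vals), 0.35)
  expect_gt(mean(lag_vals), 0.9)
})

test_that("tidy() returns one row per unordered pair", {
  v <- random_pli_values(6, seed = 30)
  td <- tidy(fixture_pli_matrix(v))
  expect_identical(nrow(td), 15L)
  expect_identical(td$band, rep("alpha", 15))
})
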