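make_rec <- function(signal, fs = 600, run_id = 1L) {
  structure(list(signal = signal, fs = fs, run_id = run_id, subject_id = "S1"),
            class = "eeg_recording")
}

test_that("normalizer matches the two-point closed form and standardizes training data", {
  rec <- make_rec(matrix(c(1, 10, 3, 20), 2, 2))   # channel 1: {1, 3}; channel 2: {10, 20}
  st <- fit_normalizer(list(rec))
  expect_equal(st$mu, c(2, 15))
  expect_equal(st$sigma, c(1, 5))                  # population convention
  test_rec <- make_rec(matrix(c(5, 15), 2, 1))
  z <- apply_normalizer(test_rec, st)
  expect_equal(z$signal[, 1], c(3, 0))

  # applying training stats to the training data itself: mean 0, sd 1
  zr <- apply_normalizer(rec, st)
  expect_equal(rowMeans(zr$signal), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(zr$signal^2)), c(1, 1), tolerance = 1e-12)

  const <- make_rec(rbind(rnorm(50), rep(7, 50)))
  err <- expect_error(fit_normalizer(list(const)), class = "scbam_flagged_channel")
  expect_equal(err$channels, 2L)
})

test_that("common average reference zeroes the spatial mean and is idempotent", {
  expect_equal(apply_car(make_rec(matrix(3, 4, 10)))$signal, matrix(0, 4, 10))

  ab <- make_rec(rbind(1:5, 11:15))
  expect_equal(apply_car(ab)$signal, rbind(-rep(5, 5), rep(5, 5)))

  set.seed(1)
  r <- make_rec(matrix(rnorm(400), 4, 100))
  out <- apply_car(r)
  expect_lt(max(abs(colMeans(out$signal))), 1e-12)
  expect_equal(apply_car(out)$signal, out$signal)

  expect_error(apply_car(make_rec(matrix(1, 1, 10))), class = "scbam_invalid_argument")
})

test_that("the notch cascade removes line harmonics and spares the passband", {
  fs <- 600
  t <- seq(0, 5, by = 1 / fs)
  for (f in c(60, 120, 180, 240)) {
    rec <- make_rec(matrix(sin(2 * pi * f * t), 1))
    out <- apply_notch_cascade(rec)
    expect_lt(sqrt(mean(out$signal^2)), 0.01)      # >= 40 dB at every notch
  }
  rec10 <- make_rec(matrix(sin(2 * pi * 10 * t), 1))
  out10 <- apply_notch_cascade(rec10)
  expect_equal(sqrt(mean(out10$signal^2)), sqrt(mean(rec10$signal^2)),
               tolerance = 0.01)                   # < 1 dB in the passband

  # linearity
  set.seed(2)
  rec <- make_rec(matrix(rnorm(3000), 1))
  y1 <- apply_notch_cascade(make_rec(3.7 * rec$signal))$signal
  y2 <- 3.7 * apply_notch_cascade(rec)$signal
  expect_equal(y1, y2, tolerance = 1e-9)

  expect_error(apply_notch_cascade(make_rec(matrix(rnorm(100), 1), fs = 400)),
               class = "scbam_invalid_argument")   # 240 Hz above Nyquist
})

test_that("artifact screening flags spiked channels and rejects bad runs", {
  set.seed(3)
  sig <- matrix(rnorm(16 * 6000), 16, 6000)
  sig[5, 1234] <- 12                               # one 12-sigma spike
  flags <- detect_artifacts(make_rec(sig))
  expect_identical(sort(unique(flags$channel[flags$flagged])), 5L)
  expect_true(reject_runs(flags, 0.10)$keep)       # 1/16 < 10%

  sig2 <- matrix(rnorm(256 * 6000), 256, 6000)
  sig2[1:30, 100] <- 15                            # 30 of 256 channels bad
  dec <- reject_runs(detect_artifacts(make_rec(sig2)), 0.10)
  expect_false(dec$keep)                           # 0.117 > 0.10
  expect_equal(dec$bad_channels, 1:30)

  clean <- detect_artifacts(make_rec(matrix(rnorm(8 * 3000), 8, 3000)))
  expect_true(reject_runs(clean)$keep)
})

test_that("windowing follows the overlap arithmetic and inherits labels", {
  rec <- make_rec(matrix(rnorm(2 * 10000), 2, 10000))
  ev <- data.frame(onset_sample = c(100L, 4000L), duration_samples = c(3000L, 3000L),
                   label = c(2L, 4L), trial_id = c(1L, 2L))
  ws <- window_trials(rec, ev, 600, 300)
  expect_equal(dim(ws$data), c(18, 2, 600))        # 9 windows per 3000-sample trial
  expect_equal(ws$labels, rep(c(2L, 4L), each = 9))
  expect_equal(ws$trial_ids, rep(1:2, each = 9))
  # first window is exactly the trial's first 600 samples (0-based half-open)
  expect_equal(ws$data[1, , ], rec$signal[, 101:700])
  expect_equal(ws$data[2, , ], rec$signal[, 401:1000])

  ev1 <- data.frame(onset_sample = 0L, duration_samples = 600L, label = 1L, trial_id = 1L)
  expect_equal(dim(window_trials(rec, ev1, 600, 300)$data)[1], 1)

  ev3 <- data.frame(onset_sample = 0L, duration_samples = 1200L, label = 1L, trial_id = 1L)
  ws3 <- window_trials(rec, ev3, 600, 300)
  expect_equal(dim(ws3$data)[1], 3)                # onsets 0, 300, 600
  expect_equal(ws3$data[3, , ], rec$signal[, 601:1200])

  short <- data.frame(onset_sample = 0L, duration_samples = 500L, label = 1L, trial_id = 1L)
  expect_error(window_trials(rec, short, 600, 300), class = "scbam_invalid_argument")
})

test_that("fitted statistics never depend on test runs", {
  m <- tiny_montage(3)
  spec <- tiny_spec(seed = 4, n_runs = 3, trials_per_run = 5)
  sess <- simulate_session(spec, m)
  st1 <- fit_normalizer(lapply(sess[1:2], `[[`, "recording"))
  sess[[3]]$recording$signal <- sess[[3]]$recording$signal * 100 + 5
  st2 <- fit_normalizer(lapply(sess[1:2], `[[`, "recording"))
  expect_identical(rlang::hash(st1), rlang::hash(st2))
})
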