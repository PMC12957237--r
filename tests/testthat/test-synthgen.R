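test_that("grid montages have the right geometry", {
  m <- make_grid_montage(16, 16, 8.6)
  expect_equal(nrow(m$coords), 256)
  # row-major neighbours sit one pitch apart
  expect_equal(sqrt(diff(m$coords$x[1:2])^2 + diff(m$coords$y[1:2])^2), 8.6)

  m1 <- make_grid_montage(1, 1, 8.6)
  expect_equal(nrow(m1$coords), 1)
  expect_equal(c(m1$coords$x, m1$coords$y), c(0, 0))

  # brute-force pairwise-distance oracle on the 2 x 3 grid
  m23 <- make_grid_montage(2, 3, 10)
  d <- as.matrix(dist(m23$coords[, c("x", "y")]))
  expect_equal(nrow(m23$coords), 6)
  expect_equal(max(d), 10 * sqrt(1^2 + 2^2))

  expect_error(make_grid_montage(0, 4, 8.6), class = "scbam_invalid_argument")
  expect_error(make_grid_montage(4, 4, -1), class = "scbam_invalid_argument")
})

test_that("simulation spec enforces its invariants", {
  expect_error(sim_spec(effect_size = -1), class = "scbam_invalid_argument")
  expect_error(sim_spec(trials_per_run = 23), class = "scbam_invalid_argument")
  expect_error(sim_spec(fs = 250), class = "scbam_invalid_argument")  # band edge >= Nyquist
})

test_that("a simulated run follows the cueing protocol and is reproducible", {
  m <- make_grid_montage(3, 3, 8.6)
  spec <- sim_spec(n_runs = 2, trials_per_run = 25, seed = 5)
  r <- simulate_run(spec, m, 1)
  expect_equal(nrow(r$events), 25)
  expect_true(all(table(r$events$label) == 5))
  expect_equal(r$events$duration_samples, rep(3000, 25))

  # bookkeeping: baseline + rests + tasks fill the recording exactly
  n <- ncol(r$recording$signal)
  rests <- n - 30 * 600 - sum(r$events$duration_samples)
  expect_gte(rests, 25 * 3 * 600)
  expect_lte(rests, 25 * 4 * 600)
  expect_gte(r$events$onset_sample[1], 30 * 600 + 3 * 600)
  expect_true(all(r$events$onset_sample + r$events$duration_samples <= n))

  # bit-identical under the same spec and run index
  expect_identical(simulate_run(spec, m, 1), r)
  # a different run index gives different data and labels stay balanced
  r2 <- simulate_run(spec, m, 2)
  expect_false(identical(r2$recording$signal, r$recording$signal))
  expect_true(all(table(r2$events$label) == 5))
})

test_that("pure line-noise runs peak at the line frequency", {
  m <- make_grid_montage(2, 2, 8.6)
  spec <- sim_spec(n_runs = 1, trials_per_run = 5, effect_size = 0,
                   noise_sd = 0, artifact_rate = 0, line_amp = 1, seed = 3)
  r <- simulate_run(spec, m, 1)
  x <- r$recording$signal[1, ]
  # periodogram oracle: a sinusoid concentrates its power at its frequency bin
  pg <- Mod(fft(x))^2
  freqs <- (seq_along(pg) - 1) * 600 / length(pg)
  half <- freqs < 300
  peak <- freqs[half][which.max(pg[half])]
  expect_lt(abs(peak - 60), 0.05)
})

test_that("zero effect size removes all label dependence from the signal", {
  m <- make_grid_montage(3, 3, 8.6)
  s0 <- sim_spec(n_runs = 1, trials_per_run = 10, effect_size = 0, seed = 9)
  s1 <- sim_spec(n_runs = 1, trials_per_run = 10, effect_size = 0.5, seed = 9)
  r0 <- simulate_run(s0, m, 1)
  r1 <- simulate_run(s1, m, 1)
  # identical seeds: the null signal differs from the effect signal only
  # during task periods of the modulated patches
  expect_identical(r0$events, r1$events)
  expect_false(identical(r0$recording$signal, r1$recording$signal))
  pre_task <- seq_len(r0$events$onset_sample[1] - 600)
  expect_equal(r0$recording$signal[, pre_task], r1$recording$signal[, pre_task])
})

test_that("fixtures round-trip bit-exactly and validate on read", {
  m <- make_grid_montage(2, 1, 8.6)
  rec <- structure(list(signal = matrix(c(pi, exp(1), 1/3, sqrt(2), -1e-17, 42), 2, 3),
                        fs = 600, montage = m, run_id = 1L, subject_id = "S1"),
                   class = "eeg_recording")
  ev <- data.frame(onset_sample = 0L, duration_samples = 2L, label = 1L, trial_id = 1L)
  path <- withr::local_tempdir()
  write_fixture(rec, ev, path)
  back <- read_fixture(path)
  expect_identical(back$recording$signal, rec$signal)
  expect_equal(back$events$onset_sample, ev$onset_sample)
  expect_equal(back$recording$fs, 600)
  expect_equal(back$recording$montage$pitch_mm, 8.6)

  bad <- data.frame(onset_sample = 2L, duration_samples = 5L, label = 1L, trial_id = 1L)
  expect_error(write_fixture(rec, bad, withr::local_tempdir()),
               class = "scbam_format_error")
})

test_that("session fixtures and BIDS event export round-trip", {
  m <- tiny_montage(2)
  spec <- sim_spec(n_runs = 2, trials_per_run = 5, seed = 2)
  sess <- simulate_session(spec, m)
  path <- withr::local_tempdir()
  write_session_fixture(sess, path)
  back <- read_session_fixture(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$recording$signal, sess[[1]]$recording$signal)
  expect_identical(back[[2]]$events$label, sess[[2]]$events$label)

  tsv <- file.path(path, "events_bids.tsv")
  export_bids_events(sess[[1]]$events, fs = 600, file = tsv)
  bids <- read.delim(tsv)
  expect_equal(names(bids), c("onset", "duration", "trial_type"))
  expect_equal(bids$duration, rep(5, 5))
})
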