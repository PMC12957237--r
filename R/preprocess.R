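#' Per-channel z-score normalization fitted on training runs
#'
#' Channel means and standard deviations (population convention, denominator
#' `N`) are estimated from the concatenated training recordings only and then
#' applied unchanged to any recording, preventing leakage of test-run
#' statistics into the fitted pipeline.
#'
#' @param recordings_train Nonempty list of `eeg_recording` objects.
#' @return `fit_normalizer()`: an object of class `scbam_normalizer` with
#'   per-channel `mu` and `sigma`. `apply_normalizer()`: the recording with
#'   each channel standardized by the fitted statistics.
#' @export
fit_normalizer <- function(recordings_train) {
  if (!length(recordings_train)) stop_invalid("need at least one training recording")
  sig <- do.call(cbind, lapply(recordings_train, function(r) r$signal))
  mu <- rowMeans(sig)
  sigma <- sqrt(rowMeans((sig - mu)^2))
  bad <- which(sigma <= 0 | !is.finite(sigma))
  if (length(bad)) stop_flagged_channels(bad)
  structure(list(mu = mu, sigma = sigma), class = "scbam_normalizer")
}

#' @rdname fit_normalizer
#' @param rec An `eeg_recording`.
#' @param stats A fitted `scbam_normalizer`.
#' @export
apply_normalizer <- function(rec, stats) {
  stopifnot(inherits(stats, "scbam_normalizer"))
  if (nrow(rec$signal) != length(stats$mu))
    stop_invalid("recording has %d channels, normalizer %d", nrow(rec$signal), length(stats$mu))
  rec$signal <- (rec$signal - stats$mu) / stats$sigma
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous across-channel mean from every channel, so the
#' spatial mean of the output is zero at each sample. Idempotent.
#'
#' @param rec An `eeg_recording` with at least two channels.
#' @return The re-referenced recording.
#' @export
apply_car <- function(rec) {
  if (nrow(rec$signal) < 2) stop_invalid("CAR needs at least 2 channels")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal), `-`)
  rec
}

#' Power-line notch filter cascade
#'
#' Zero-phase 4th-order Butterworth band-stop filters at the line frequency and
#' its harmonics, applied in cascade. With the defaults (60 Hz line, 4
#' harmonics) the notch frequencies are 60, 120, 180 and 240 Hz.
#'
#' @param rec An `eeg_recording`.
#' @param line_hz Line frequency in Hz.
#' @param n_harmonics Number of notches including the fundamental.
#' @param order Transfer-function order of each band-stop section.
#' @param half_width_hz Half-width of each notch in Hz.
#' @return The filtered recording.
#' @export
apply_notch_cascade <- function(rec, line_hz = 60, n_harmonics = 4,
                                order = 4, half_width_hz = 1) {
  freqs <- line_hz * seq_len(n_harmonics)
  if (any(freqs + half_width_hz >= rec$fs / 2))
    stop_invalid("notch harmonic at %g Hz reaches Nyquist (%g Hz)",
                 max(freqs), rec$fs / 2)
  X <- t(rec$signal)
  for (f in freqs) {
    filt <- butter_bandstop(f - half_width_hz, f + half_width_hz, rec$fs, order)
    X <- zero_phase_filter_mat(filt, X)
  }
  rec$signal <- t(X)
  rec
}

#' Artifact detection and run rejection
#'
#' The run is divided into non-overlapping segments (`segment_s` seconds). For
#' each channel the segment statistic is the maximum absolute z-score computed
#' with that channel's run-wide mean and standard deviation; a segment is
#' flagged when the statistic exceeds `z_thresh`. A run is rejected when the
#' fraction of channels having at least one flagged segment exceeds
#' `channel_frac`.
#'
#' @param rec An `eeg_recording`.
#' @param z_thresh Flagging threshold on the segment statistic.
#' @param segment_s Segment length in seconds.
#' @return `detect_artifacts()`: data.frame with one row per
#'   (channel, segment): `channel`, `segment`, `stat`, `flagged`.
#' @export
detect_artifacts <- function(rec, z_thresh = 6, segment_s = 1) {
  seg_len <- round(segment_s * rec$fs)
  if (seg_len < 1) stop_invalid("segment_s x fs must be >= 1 sample")
  n <- ncol(rec$signal)
  n_seg <- n %/% seg_len
  mu <- rowMeans(rec$signal)
  sigma <- apply(rec$signal, 1, stats::sd)
  sigma[sigma == 0] <- Inf                         # constant channel can't exceed any threshold
  z <- abs((rec$signal - mu) / sigma)
  stat <- vapply(seq_len(n_seg), function(s) {
    idx <- seq((s - 1L) * seg_len + 1L, s * seg_len)
    apply(z[, idx, drop = FALSE], 1, max)
  }, numeric(nrow(z)))
  flags <- data.frame(
    channel = rep(seq_len(nrow(z)), n_seg),
    segment = rep(seq_len(n_seg), each = nrow(z)),
    stat = as.vector(stat))
  flags$flagged <- flags$stat > z_thresh
  flags
}

#' @rdname detect_artifacts
#' @param flags Output of `detect_artifacts()`.
#' @param channel_frac Maximum tolerated fraction of bad channels.
#' @return `reject_runs()`: list with `keep` (logical), `bad_channels`,
#'   `bad_fraction`.
#' @export
reject_runs <- function(flags, channel_frac = 0.10) {
  bad <- sort(unique(flags$channel[flags$flagged]))
  n_chan <- length(unique(flags$channel))
  frac <- if (n_chan) length(bad) / n_chan else 0
  list(keep = frac <= channel_frac, bad_channels = bad, bad_fraction = frac)
}

#' Chop trials into overlapping fixed-length windows
#'
#' Each event's samples (0-based, half-open `[onset, onset + duration)`) are cut
#' into windows of `window_len` samples advancing by `step`; a 3000-sample trial
#' with the default 600/300 yields 9 windows. Windows inherit the trial's label
#' and identity.
#'
#' @param rec An `eeg_recording`.
#' @param events Event table for the recording.
#' @param window_len,step Window length and hop in samples.
#' @return A `scbam_window_set`: list with `data` (windows x channels x
#'   samples array), `labels`, `trial_ids`, `run_ids`, `window_len`, `step`.
#' @export
window_trials <- function(rec, events, window_len = 600, step = 300) {
  validate_events(events, ncol(rec$signal))
  if (step < 1) stop_invalid("step must be >= 1")
  if (any(events$duration_samples < window_len))
    stop_invalid("window_len (%d) exceeds the shortest trial (%d samples)",
                 window_len, min(events$duration_samples))
  n_chan <- nrow(rec$signal)
  per_trial <- (events$duration_samples - window_len) %/% step + 1L
  total <- sum(per_trial)
  data <- array(0, dim = c(total, n_chan, window_len))
  labels <- integer(total); trial_ids <- integer(total)
  w <- 0L
  for (i in seq_len(nrow(events))) {
    for (k in seq_len(per_trial[i])) {
      w <- w + 1L
      start <- events$onset_sample[i] + (k - 1L) * step
      data[w, , ] <- rec$signal[, seq(start + 1L, start + window_len)]
      labels[w] <- events$label[i]
      trial_ids[w] <- events$trial_id[i]
    }
  }
  structure(list(data = data, labels = labels, trial_ids = trial_ids,
                 run_ids = rep(rec$run_id, total),
                 window_len = window_len, step = step),
            class = "scbam_window_set")
}

#' Concatenate window sets
#'
#' @param ... `scbam_window_set` objects with identical window geometry.
#' @return A single combined `scbam_window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "scbam_window_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "scbam_window_set")))
  wl <- unique(vapply(sets, function(s) s$window_len, numeric(1)))
  st <- unique(vapply(sets, function(s) s$step, numeric(1)))
  if (length(wl) != 1L || length(st) != 1L)
    stop_invalid("window sets have inconsistent window_len/step")
  total <- sum(vapply(sets, function(s) dim(s$data)[1], numeric(1)))
  n_chan <- dim(sets[[1]]$data)[2]
  data <- array(0, dim = c(total, n_chan, wl))
  at <- 0L
  for (s in sets) {
    k <- dim(s$data)[1]
    if (k) data[at + seq_len(k), , ] <- s$data
    at <- at + k
  }
  structure(list(data = data,
                 labels = unlist(lapply(sets, `[[`, "labels")),
                 trial_ids = unlist(lapply(sets, `[[`, "trial_ids")),
                 run_ids = unlist(lapply(sets, `[[`, "run_ids")),
                 window_len = wl, step = st),
            class = "scbam_window_set")
}

subset_windows <- function(ws, idx) {
  structure(list(data = ws$data[idx, , , drop = FALSE],
                 labels = ws$labels[idx], trial_ids = ws$trial_ids[idx],
                 run_ids = ws$run_ids[idx],
                 window_len = ws$window_len, step = ws$step),
            class = "scbam_window_set")
}

#' Full preprocessing of a session
#'
#' Applies the preprocessing chain in order: z-score (fitted on the training
#' runs only), common average reference, notch cascade, artifact-based run
#' rejection, then overlapped windowing of the task trials. The 30 s baseline
#' is excluded because no event covers it.
#'
#' @param session List of per-run lists (`recording`, `events`), e.g. from
#'   [simulate_session()].
#' @param train_runs Run ids used to fit the normalizer.
#' @param window_len,step Windowing geometry in samples.
#' @param z_thresh,channel_frac Artifact rejection parameters.
#' @return List with `windows` (a combined `scbam_window_set`), `normalizer`,
#'   `kept_runs`, `rejected_runs`.
#' @export
preprocess_session <- function(session, train_runs, window_len = 600, step = 300,
                               z_thresh = 6, channel_frac = 0.10) {
  run_ids <- vapply(session, function(s) s$recording$run_id, integer(1))
  if (!all(train_runs %in% run_ids)) stop_invalid("train_runs not all present in session")
  norm <- fit_normalizer(lapply(session[run_ids %in% train_runs], `[[`, "recording"))
  kept <- list(); rejected <- integer(0)
  for (s in session) {
    rec <- apply_normalizer(s$recording, norm)
    rec <- apply_car(rec)
    rec <- apply_notch_cascade(rec)
    dec <- reject_runs(detect_artifacts(rec), channel_frac)
    if (!dec$keep) { rejected <- c(rejected, rec$run_id); next }
    kept[[length(kept) + 1L]] <- window_trials(rec, s$events, window_len, step)
  }
  if (!length(kept)) stop_invalid("all runs rejected by artifact screening")
  list(windows = bind_windows(kept), normalizer = norm,
       kept_runs = setdiff(run_ids, rejected), rejected_runs = rejected)
}
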