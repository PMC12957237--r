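#' Simulation specification for synthetic uHD-EEG finger-extension sessions
#'
#' Describes a synthetic recording session mimicking a cued finger-extension
#' protocol on a high-density electrode grid: each run opens with a 30 s
#' baseline, then alternates rest periods (3-4 s, uniform) with 5 s task
#' periods. Each of the `n_classes` fingers is cued equally often per run in a
#' pseudo-random order. Class-dependent activity is a band-limited oscillation
#' mixed through a Gaussian spatial patch whose envelope grows by `effect_size`
#' during that class's task periods; adjacent class patches are placed on
#' adjacent grid sites so that misclassifications concentrate on neighbouring
#' fingers, as observed in real sensorimotor recordings. Background noise has a
#' 1/f power spectrum; power-line contamination at `line_hz` and its harmonics
#' and sparse high-amplitude artifact spikes are added on top.
#'
#' @param n_runs Number of runs per subject.
#' @param trials_per_run Cued extensions per run; must be divisible by `n_classes`.
#' @param task_s Task (extension) duration in seconds.
#' @param rest_s_range Length-2 numeric, uniform range of rest durations (s).
#' @param baseline_s Baseline period prepended to each run (s).
#' @param fs Sampling rate in Hz; must exceed twice the highest source band edge.
#' @param n_classes Number of fingers/classes.
#' @param effect_size Dimensionless amplitude increase of the class oscillation
#'   envelope during its task periods (0 = no class information).
#' @param source_bands List of `c(low, high)` Hz per class.
#' @param source_centers Optional per-class `(x, y)` patch centres in mm; the
#'   default places the classes contiguously along the grid's middle row.
#' @param patch_sigma_mm Spatial standard deviation of the Gaussian patch (mm).
#' @param line_hz,line_amp Power-line frequency (Hz) and fundamental amplitude;
#'   harmonics up to the 4th are added with amplitude `line_amp / harmonic`.
#' @param artifact_rate Expected artifact spikes per channel-second.
#' @param noise_sd Standard deviation of the 1/f background noise.
#' @param n_subjects Number of subjects (used by [simulate_session()] callers).
#' @param seed Integer seed; together with the run index it makes every run
#'   bit-reproducible.
#'
#' @return An object of class `scbam_sim_spec`.
#' @export
sim_spec <- function(n_runs = 10, trials_per_run = 25, task_s = 5,
                     rest_s_range = c(3, 4), baseline_s = 30, fs = 600,
                     n_classes = 5, effect_size = 1,
                     source_bands = list(c(8, 12), c(12, 30), c(30, 50),
                                         c(75, 115), c(125, 150)),
                     source_centers = NULL, patch_sigma_mm = 12,
                     line_hz = 60, line_amp = 2, artifact_rate = 1e-4,
                     noise_sd = 10, n_subjects = 1, seed = 1L) {
  if (effect_size < 0) stop_invalid("effect_size must be >= 0")
  if (trials_per_run %% n_classes != 0)
    stop_invalid("trials_per_run (%d) must be divisible by n_classes (%d) for balanced cueing",
                 trials_per_run, n_classes)
  if (length(source_bands) != n_classes)
    stop_invalid("need one source band per class")
  max_edge <- max(vapply(source_bands, max, numeric(1)))
  if (fs <= 2 * max_edge)
    stop_invalid("fs (%g) must exceed twice the highest band edge (%g)", fs, max_edge)
  structure(
    list(n_runs = n_runs, trials_per_run = trials_per_run, task_s = task_s,
         rest_s_range = rest_s_range, baseline_s = baseline_s, fs = fs,
         n_classes = n_classes, effect_size = effect_size,
         source_bands = source_bands, source_centers = source_centers,
         patch_sigma_mm = patch_sigma_mm, line_hz = line_hz,
         line_amp = line_amp, artifact_rate = artifact_rate,
         noise_sd = noise_sd, n_subjects = n_subjects, seed = as.integer(seed)),
    class = "scbam_sim_spec")
}

# Deterministic sub-seed per (seed, run); kept below 2^31 - 1.
run_seed <- function(seed, run_index) {
  ((as.numeric(seed) %% 65521) * 20011 + run_index * 7919) %% 2147483647
}

# Evaluate code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 1/f-shaped Gaussian noise, one column per channel, each scaled to sd = noise_sd.
pink_noise <- function(n, n_chan, noise_sd) {
  nfft <- stats::nextn(n, c(2, 3, 5))     # composite length keeps the FFT fast
  W <- matrix(stats::rnorm(nfft * n_chan), nfft, n_chan)
  Fw <- stats::mvfft(W)
  freq <- c(1, seq_len(nfft - 1))         # guard DC; symmetric bins share scale
  freq <- pmin(freq, nfft - freq + 1)
  scale <- 1 / sqrt(freq)
  X <- Re(stats::mvfft(Fw * scale, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
  sds <- apply(X, 2, stats::sd)
  sweep(X, 2, noise_sd / sds, `*`)
}

default_source_centers <- function(spec, montage) {
  # contiguous sites along the middle row: adjacent classes get adjacent patches
  mid_row <- ceiling(montage$n_rows / 2)
  cols <- round(seq(1, montage$n_cols, length.out = spec$n_classes + 2))[2:(spec$n_classes + 1)]
  lapply(cols, function(cc) {
    e <- (mid_row - 1) * montage$n_cols + cc
    c(montage$coords$x[e], montage$coords$y[e])
  })
}

#' Simulate one run of a synthetic uHD-EEG finger-extension session
#'
#' @param spec A [sim_spec()].
#' @param montage A [make_grid_montage()] montage.
#' @param run_index Run number (1-based, `<= spec$n_runs`).
#' @param subject_id Subject label stored in the recording.
#'
#' @return A list with `recording` (class `eeg_recording`: `signal` channels x
#'   samples matrix, `fs`, `montage`, `run_id`, `subject_id`) and `events`, a
#'   data.frame with 0-based `onset_sample`, `duration_samples`, `label`
#'   (1..n_classes) and session-unique `trial_id`.
#' @export
simulate_run <- function(spec, montage, run_index, subject_id = "S1") {
  stopifnot(inherits(spec, "scbam_sim_spec"), inherits(montage, "scbam_montage"))
  if (run_index < 1 || run_index > spec$n_runs)
    stop_invalid("run_index %d outside 1..%d", run_index, spec$n_runs)
  fs <- spec$fs
  n_chan <- n_electrodes(montage)

  with_seed(run_seed(spec$seed, run_index), {
    labels <- sample(rep(seq_len(spec$n_classes), spec$trials_per_run / spec$n_classes))
    rest_samp <- round(stats::runif(spec$trials_per_run,
                                    spec$rest_s_range[1], spec$rest_s_range[2]) * fs)
    task_samp <- round(spec$task_s * fs)
    base_samp <- round(spec$baseline_s * fs)

    onsets <- base_samp + cumsum(rest_samp) + task_samp * (seq_along(rest_samp) - 1L)
    n <- base_samp + sum(rest_samp) + task_samp * spec$trials_per_run

    sig_t <- pink_noise(n, n_chan, spec$noise_sd)   # time x channels

    centers <- spec$source_centers %||% default_source_centers(spec, montage)
    for (k in seq_len(spec$n_classes)) {
      bp <- butter_bandpass(spec$source_bands[[k]][1], spec$source_bands[[k]][2], fs)
      osc <- zero_phase_filter_vec(bp, stats::rnorm(n))
      osc <- osc / stats::sd(osc) * spec$noise_sd
      env <- rep(1, n)
      for (i in which(labels == k)) {
        idx <- seq(onsets[i] + 1L, onsets[i] + task_samp)
        env[idx] <- env[idx] + spec$effect_size
      }
      d2 <- (montage$coords$x - centers[[k]][1])^2 + (montage$coords$y - centers[[k]][2])^2
      w <- exp(-d2 / (2 * spec$patch_sigma_mm^2))
      sig_t <- sig_t + tcrossprod(osc * env, w)
    }

    if (spec$line_amp > 0) {
      tvec <- (seq_len(n) - 1) / fs
      gains <- 1 + 0.05 * stats::rnorm(n_chan)
      line <- numeric(n)
      for (h in 1:4) {
        f <- h * spec$line_hz
        if (f < fs / 2)
          line <- line + (spec$line_amp / h) * sin(2 * pi * f * tvec + stats::runif(1, 0, 2 * pi))
      }
      sig_t <- sig_t + tcrossprod(line, gains)
    }

    if (spec$artifact_rate > 0) {
      pulse_len <- max(2L, round(0.05 * fs))
      pulse <- 15 * spec$noise_sd * (1 - cos(2 * pi * seq_len(pulse_len) / pulse_len)) / 2
      for (ch in seq_len(n_chan)) {
        n_art <- stats::rpois(1, spec$artifact_rate * n / fs)
        if (n_art > 0) {
          starts <- sample.int(n - pulse_len, n_art)
          signs <- sample(c(-1, 1), n_art, replace = TRUE)
          for (j in seq_len(n_art)) {
            idx <- seq(starts[j], starts[j] + pulse_len - 1L)
            sig_t[idx, ch] <- sig_t[idx, ch] + signs[j] * pulse
          }
        }
      }
    }

    events <- data.frame(
      onset_sample = onsets,
      duration_samples = rep(task_samp, spec$trials_per_run),
      label = labels,
      trial_id = (run_index - 1L) * spec$trials_per_run + seq_len(spec$trials_per_run)
    )
    recording <- structure(
      list(signal = t(sig_t), fs = fs, montage = montage,
           run_id = as.integer(run_index), subject_id = subject_id),
      class = "eeg_recording")
    list(recording = recording, events = events)
  })
}

#' Simulate a full multi-run session
#'
#' @inheritParams simulate_run
#' @return A list of per-run lists, each with `recording` and `events`.
#' @export
simulate_session <- function(spec, montage, subject_id = "S1") {
  lapply(seq_len(spec$n_runs), function(r) simulate_run(spec, montage, r, subject_id))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s run %d: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$run_id, nrow(x$signal), ncol(x$signal), x$fs))
  invisible(x)
}
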