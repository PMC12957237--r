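#' Write and read plain-text recording fixtures
#'
#' A fixture is a self-describing directory in a BIDS-flavoured layout:
#' `meta.json` (sampling rate, grid shape, pitch, identities), `signal.tsv`
#' (samples x channels, full `%.17g` precision so doubles round-trip
#' bit-exactly) and `events.tsv` (`onset_sample`, `duration_samples`, `label`,
#' `trial_id`). [export_bids_events()] additionally writes a BIDS-style events
#' table in seconds.
#'
#' @param recording An `eeg_recording` (see [simulate_run()]).
#' @param events Event table (data.frame with `onset_sample`,
#'   `duration_samples`, `label`, `trial_id`).
#' @param path Directory to create/overwrite.
#'
#' @return `write_fixture()` returns `path` invisibly; `read_fixture()` returns
#'   a list with `recording` and `events` identical to what was written.
#' @export
write_fixture <- function(recording, events, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  validate_events(events, ncol(recording$signal))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- recording$montage
  meta <- list(
    fs = recording$fs, pitch_mm = m$pitch_mm, n_rows = m$n_rows,
    n_cols = m$n_cols, origin_label = m$origin_label,
    run_id = recording$run_id, subject_id = recording$subject_id,
    n_channels = nrow(recording$signal), n_samples = ncol(recording$signal))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  sig <- t(recording$signal)                       # samples x channels
  chr <- matrix(sprintf("%.17g", sig), nrow(sig), ncol(sig))
  colnames(chr) <- sprintf("ch%03d", seq_len(ncol(chr)))
  data.table::fwrite(data.table::as.data.table(chr),
                     file.path(path, "signal.tsv"), sep = "\t")
  data.table::fwrite(events, file.path(path, "events.tsv"), sep = "\t")
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    stop_format("no meta.json under '%s'", path, field = "meta.json")
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (f in c("fs", "pitch_mm", "n_rows", "n_cols", "n_channels", "n_samples"))
    if (is.null(meta[[f]])) stop_format("meta.json missing field '%s'", f, field = f)
  sig_dt <- data.table::fread(file.path(path, "signal.tsv"),
                              sep = "\t", colClasses = "character")
  sig <- t(vapply(sig_dt, as.numeric, numeric(nrow(sig_dt))))  # channels x samples
  if (nrow(sig) != meta$n_channels || ncol(sig) != meta$n_samples)
    stop_format("signal.tsv is %d x %d but meta declares %d channels x %d samples",
                nrow(sig), ncol(sig), meta$n_channels, meta$n_samples,
                field = "signal")
  if (meta$n_rows * meta$n_cols != meta$n_channels)
    stop_format("grid %d x %d does not match %d channels",
                meta$n_rows, meta$n_cols, meta$n_channels, field = "montage")
  events <- as.data.frame(data.table::fread(file.path(path, "events.tsv"), sep = "\t"))
  validate_events(events, meta$n_samples)
  montage <- make_grid_montage(meta$n_rows, meta$n_cols, meta$pitch_mm,
                               meta$origin_label %||% "Cz")
  recording <- structure(
    list(signal = unname(sig), fs = meta$fs, montage = montage,
         run_id = as.integer(meta$run_id %||% 1L),
         subject_id = meta$subject_id %||% "S1"),
    class = "eeg_recording")
  list(recording = recording, events = events)
}

validate_events <- function(events, n_samples) {
  need <- c("onset_sample", "duration_samples", "label", "trial_id")
  missing <- setdiff(need, names(events))
  if (length(missing))
    stop_format("events table missing column(s): %s",
                paste(missing, collapse = ", "), field = missing[1])
  bad <- which(events$onset_sample + events$duration_samples > n_samples)
  if (length(bad))
    stop_format("event(s) %s extend beyond the signal end (%d samples)",
                paste(bad, collapse = ", "), n_samples, field = "onset_sample")
  if (any(events$onset_sample < 0))
    stop_format("negative event onset", field = "onset_sample")
  invisible(events)
}

#' @rdname write_fixture
#' @param fs Sampling rate used to convert samples to seconds.
#' @param file Output TSV path.
#' @param class_names Optional labels used for `trial_type`.
#' @export
export_bids_events <- function(events, fs, file,
                               class_names = c("thumb", "index", "middle", "ring", "little")) {
  bids <- data.frame(
    onset = events$onset_sample / fs,
    duration = events$duration_samples / fs,
    trial_type = class_names[events$label])
  data.table::fwrite(bids, file, sep = "\t")
  invisible(file)
}
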