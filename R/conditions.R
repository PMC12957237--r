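# Structured error helpers. Every user-facing failure mode in the package maps to
# one of these condition classes so callers (and tests) can discriminate on class
# rather than on message text.

stop_invalid <- function(msg, ..., call. = FALSE) {
  rlang::abort(sprintf(msg, ...), class = "scbam_invalid_argument")
}

stop_format <- function(msg, ..., field = NULL) {
  rlang::abort(sprintf(msg, ...),
               class = "scbam_format_error", field = field)
}

stop_numerical <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "scbam_numerical_error")
}

stop_flagged_channels <- function(channels) {
  rlang::abort(
    sprintf("channel(s) with zero variance: %s",
            paste(channels, collapse = ", ")),
    class = "scbam_flagged_channel", channels = channels)
}

stop_undefined_statistic <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "scbam_undefined_statistic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
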