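#' EEG recording containers
#'
#' `raw_recording()` holds a uniformly sampled single-channel EEG trace in
#' microvolts together with its sampling rate, ADC input range and Zeitgeber
#' alignment. `clean_recording()` is the post-processed form: exactly 200 Hz,
#' band-limited, with a provenance list recording every applied step and its
#' parameters.
#'
#' @param samples Numeric vector, microvolts.
#' @param fs Sampling rate in Hz.
#' @param input_range_uV ADC half-range in microvolts (clipping saturates
#'   at this level).
#' @param zt0_offset ZT hour of the first sample.
#' @param subject_id Optional subject identifier.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, input_range_uV = 2e5, zt0_offset = 0,
                          subject_id = NA_character_) {
  if (fs <= 0) stop_user("`fs` must be positive")
  structure(list(samples = as.numeric(samples), fs = fs,
                 input_range_uV = input_range_uV, zt0_offset = zt0_offset,
                 subject_id = subject_id, provenance = list()),
            class = "raw_recording")
}

#' @rdname raw_recording
#' @param rec A `raw_recording` at exactly 200 Hz.
#' @export
clean_recording <- function(rec) {
  if (abs(rec$fs - 200) > 1e-9) stop_user("clean recordings must be at 200 Hz")
  class(rec) <- c("clean_recording", "raw_recording")
  rec
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("%s: %d samples @ %g Hz (%.2f h), ZT%g start, +/-%g uV range\n",
              if (inherits(x, "clean_recording")) "Clean EEG recording"
              else "Raw EEG recording",
              length(x$samples), x$fs, length(x$samples) / x$fs / 3600,
              x$zt0_offset, x$input_range_uV))
  if (length(x$provenance)) {
    cat("  steps:", paste(vapply(x$provenance, `[[`, "", "step"),
                          collapse = " -> "), "\n")
  }
  invisible(x)
}

add_provenance <- function(rec, step, params) {
  rec$provenance <- c(rec$provenance, list(c(list(step = step), params)))
  rec
}
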