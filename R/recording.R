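#' Construct a PPG recording
#'
#' A PPG recording is a tibble with columns `time_s` and `amplitude`, a
#' `sampling_rate` attribute (Hz) and an optional `subject_id`. All signal
#' verbs in the package take and return this shape, so recordings chain with
#' the pipe.
#'
#' @param amplitude Numeric vector of waveform samples (arbitrary units).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample, seconds.
#' @param subject_id Optional subject identifier.
#' @return A `ppg_recording` tibble with columns `time_s`, `amplitude`.
#' @export
#' @examples
#' rec <- ppg_recording(sin(2 * pi * 1.2 * seq(0, 10, by = 0.04)), 25)
#' sampling_rate(rec)
ppg_recording <- function(amplitude, sampling_rate, start_time = 0,
                          subject_id = NULL) {
  if (!is.numeric(amplitude) || length(amplitude) < 2L) {
    abort("`amplitude` must be a numeric vector of length >= 2.",
          class = "pulsefusion_config_error")
  }
  if (any(!is.finite(amplitude))) {
    abort("`amplitude` contains non-finite values.",
          class = "pulsefusion_config_error")
  }
  check_number(sampling_rate, "sampling_rate", lower = 0)
  out <- tibble::new_tibble(
    list(time_s = start_time + (seq_along(amplitude) - 1) / sampling_rate,
         amplitude = as.numeric(amplitude)),
    nrow = length(amplitude)
  )
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "subject_id") <- subject_id
  class(out) <- c("ppg_recording", class(tibble()))
  out
}

#' Sampling rate of a recording
#'
#' Returns the `sampling_rate` attribute when present, otherwise infers the
#' rate from the median spacing of `time_s` (robust to a recording having
#' passed through attribute-dropping data-frame verbs).
#'
#' @param recording A `ppg_recording` or any data frame with a `time_s` column.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(recording) {
  fs <- attr(recording, "sampling_rate")
  if (!is.null(fs)) return(fs)
  dt <- median(diff(recording$time_s))
  if (!is.finite(dt) || dt <= 0) {
    abort("Cannot infer a sampling rate from `time_s`.",
          class = "pulsefusion_parse_error")
  }
  1 / dt
}

subject_id_of <- function(recording) {
  attr(recording, "subject_id") %||% NA_character_
}

# Rebuild a recording around a new amplitude vector, preserving metadata.
replace_amplitude <- function(recording, amplitude) {
  ppg_recording(amplitude, sampling_rate(recording),
                start_time = recording$time_s[1],
                subject_id = attr(recording, "subject_id"))
}
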