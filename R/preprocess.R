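#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward and backward (`signal::filtfilt`), so
#' the filter is zero-phase and fiducial timings are not shifted. The default
#' band 0.5--8 Hz is the standard PPG band: it removes baseline wander and
#' drift below the slowest plausible beat while keeping the first ~10
#' harmonics of typical heart rates.
#'
#' @param recording A [ppg_recording()].
#' @param low,high Band edges, Hz; `0 < low < high < sampling_rate / 2`.
#' @param order Butterworth prototype order (applied twice by the
#'   forward-backward pass).
#' @return A filtered [ppg_recording()], same length and sampling rate.
#' @export
bandpass_filter <- function(recording, low = 0.5, high = 8, order = 4) {
  fs <- sampling_rate(recording)
  check_number(low, "low", lower = 0)
  check_number(high, "high", lower = low, upper = fs / 2,
               allow_equal_upper = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  replace_amplitude(recording,
                    signal::filtfilt(bf, recording$amplitude))
}

# Beat period (seconds) from the first prominent autocorrelation peak of the
# (assumed bandpass-filtered) signal, searched over plausible heart rates.
estimate_beat_period <- function(recording, min_bpm = 35, max_bpm = 190) {
  fs <- sampling_rate(recording)
  x <- recording$amplitude - mean(recording$amplitude)
  max_lag <- min(length(x) - 1L, ceiling(60 / min_bpm * fs))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lo <- max(2L, floor(60 / max_bpm * fs))
  if (lo + 1L > max_lag) {
    abort("Recording too short to estimate a beat period.",
          class = "pulsefusion_config_error")
  }
  cand <- lo:max_lag
  (cand[which.max(ac[cand + 1L])]) / fs
}

#' Periodic moving-average filter (PMAF)
#'
#' Denoises a quasi-periodic signal by exploiting its periodicity: the trace
#' is segmented into beat periods, each period is resampled to a common
#' length, each phase-aligned sample is replaced by the moving average over
#' the `k` adjacent periods (centered, truncated at the ends), and the result
#' is resampled back onto the original grid. Exactly periodic input passes
#' through unchanged; independent zero-mean noise is attenuated by roughly
#' `sqrt(k)`.
#'
#' @param recording A [ppg_recording()] (bandpass-filtered input recommended).
#' @param beat_period Beat period in seconds; default `NULL` estimates it
#'   from the autocorrelation peak.
#' @param k Number of adjacent periods averaged (default 3).
#' @return A denoised [ppg_recording()], same length and sampling rate. The
#'   partial head/tail outside complete periods is passed through unchanged.
#' @export
pmaf_denoise <- function(recording, beat_period = NULL, k = 3) {
  fs <- sampling_rate(recording)
  x <- recording$amplitude
  n <- length(x)
  if (is.null(beat_period)) beat_period <- estimate_beat_period(recording)
  check_number(beat_period, "beat_period", lower = 0)
  k <- as.integer(k)
  if (k < 1L) {
    abort("`k` must be >= 1.", class = "pulsefusion_config_error")
  }
  p <- beat_period * fs
  n_periods <- floor(n / p)
  if (n_periods < 3L || n_periods < k) {
    abort(paste("PMAF needs at least", max(3L, k), "full beat periods;",
                "use a shorter `k` or a longer recording."),
          class = "pulsefusion_config_error")
  }
  bounds <- round((0:n_periods) * p)
  L <- max(2L, round(p))
  phase <- seq(0, 1, length.out = L)
  # Resample each period to the common phase grid.
  mat <- vapply(seq_len(n_periods), function(j) {
    idx <- (bounds[j] + 1L):bounds[j + 1L]
    approx(seq(0, 1, length.out = length(idx)), x[idx], xout = phase)$y
  }, numeric(L))
  # Moving average across adjacent periods at fixed phase.
  sm <- t(apply(mat, 1L, moving_average, width = k))
  out <- x
  for (j in seq_len(n_periods)) {
    idx <- (bounds[j] + 1L):bounds[j + 1L]
    out[idx] <- approx(phase, sm[, j],
                       xout = seq(0, 1, length.out = length(idx)))$y
  }
  replace_amplitude(recording, out)
}

#' Sliding-window segmentation
#'
#' Splits a recording into fixed-duration windows starting at `0, hop,
#' 2 * hop, ...` seconds. The segment count convention is
#' `floor((duration - window) / hop)`: a trailing window that would touch the
#' final sample is not emitted, so a 300-s recording with a 10-s window and
#' 1-s hop yields 290 segments.
#'
#' @param recording A [ppg_recording()].
#' @param window Window length, seconds (default 10).
#' @param hop Hop between window starts, seconds (default 1).
#' @return Tibble `segment_index` (1-based), `start_s`, `end_s` (half-open),
#'   `start_index`, `end_index` (0-based half-open sample offsets).
#' @export
#' @examples
#' rec <- simulate_ppg(ppg_sim_config(duration = 300, heart_rate = 72))
#' nrow(segment_sliding_windows(rec))  # 290
segment_sliding_windows <- function(recording, window = 10, hop = 1) {
  fs <- sampling_rate(recording)
  check_number(window, "window", lower = 0)
  check_number(hop, "hop", lower = 0)
  duration <- nrow(recording) / fs
  n_seg <- max(0L, floor((duration - window) / hop))
  if (duration < window) {
    warn("Recording shorter than one window; returning zero segments.")
  }
  win_n <- round(window * fs)
  starts <- (seq_len(n_seg) - 1L) * hop
  tibble(
    segment_index = seq_len(n_seg),
    start_s = starts,
    end_s = starts + window,
    start_index = as.integer(round(starts * fs)),
    end_index = as.integer(round(starts * fs)) + win_n
  )
}

#' Extract one segment as a recording
#'
#' @param recording A [ppg_recording()].
#' @param segment One row of [segment_sliding_windows()] output (or a list
#'   with `start_index`, `end_index`).
#' @return A [ppg_recording()] holding the window's samples.
#' @export
get_segment <- function(recording, segment) {
  idx <- (segment$start_index + 1L):segment$end_index
  if (segment$start_index < 0L || segment$end_index > nrow(recording)) {
    abort("Segment indices outside the recording.",
          class = "pulsefusion_config_error")
  }
  ppg_recording(recording$amplitude[idx], sampling_rate(recording),
                start_time = recording$time_s[idx[1]],
                subject_id = attr(recording, "subject_id"))
}
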