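#' Fiducial detector configuration
#'
#' Constants of the event-related moving-average delineator and the
#' second-derivative diastolic-peak search. The two moving-average windows
#' (111 ms at peak scale, 667 ms at beat scale) and the 2% threshold offset
#' are the standard constants of this family of beat detectors.
#'
#' @param ma_peak_window Short (peak-scale) moving-average window, seconds.
#' @param ma_beat_window Long (beat-scale) moving-average window, seconds.
#' @param threshold_offset_fraction Offset added to the beat-scale average,
#'   as a fraction of the mean squared signal.
#' @param second_derivative_smoothing_window Moving-average window applied to
#'   the second derivative before the diastolic-peak search, seconds.
#' @param d2_rel_prominence Minimum height of a diastolic candidate on the
#'   inverted smoothed second derivative, relative to the beat's maximum;
#'   rejects the numerically flat inter-beat baseline.
#' @return A `detector_config` list.
#' @export
detector_config <- function(ma_peak_window = 0.111,
                            ma_beat_window = 0.667,
                            threshold_offset_fraction = 0.02,
                            second_derivative_smoothing_window = 0.120,
                            d2_rel_prominence = 0.05) {
  check_number(ma_peak_window, "ma_peak_window", lower = 0)
  check_number(ma_beat_window, "ma_beat_window", lower = ma_peak_window)
  check_number(threshold_offset_fraction, "threshold_offset_fraction",
               lower = 0, allow_equal_lower = TRUE)
  check_number(second_derivative_smoothing_window,
               "second_derivative_smoothing_window", lower = 0)
  check_number(d2_rel_prominence, "d2_rel_prominence", lower = 0,
               allow_equal_lower = TRUE)
  structure(list(ma_peak_window = ma_peak_window,
                 ma_beat_window = ma_beat_window,
                 threshold_offset_fraction = threshold_offset_fraction,
                 second_derivative_smoothing_window =
                   second_derivative_smoothing_window,
                 d2_rel_prominence = d2_rel_prominence),
            class = "detector_config")
}

fiducial_tibble <- function(recording, idx) {
  idx <- as.integer(idx)
  tibble::new_tibble(list(sample_index = idx,
                          time_s = recording$time_s[idx],
                          amplitude = recording$amplitude[idx]),
                     nrow = length(idx))
}

# Blocks-of-interest stage shared by the peak and onset detectors: clip
# negatives, square, compare a short against a long moving average plus an
# adaptive offset, and return the argmax of `x` inside each surviving block.
blocks_argmax <- function(x, fs, config) {
  n <- length(x)
  w2 <- max(2L, round(config$ma_beat_window * fs))
  if (n < w2) {
    abort("Segment shorter than the beat-scale moving-average window.",
          class = "pulsefusion_config_error")
  }
  y <- pmax(x, 0)^2
  w1 <- max(1L, round(config$ma_peak_window * fs))
  ma_peak <- moving_average(y, w1)
  ma_beat <- moving_average(y, w2)
  thr <- ma_beat + config$threshold_offset_fraction * mean(y)
  above <- ma_peak > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= w1
  purrr::map_int(which(keep), function(j) {
    idx <- starts[j]:ends[j]
    idx[which.max(x[idx])]  # ties break toward the earliest sample
  })
}

#' Detect systolic peaks (PWSP)
#'
#' Event-related moving-average delineation: the (already bandpass-filtered)
#' segment is clipped at zero and squared; blocks of interest are runs where
#' a short peak-scale moving average exceeds a long beat-scale moving average
#' plus an adaptive offset; blocks shorter than the peak-scale window are
#' rejected; the systolic peak is the argmax of the original waveform inside
#' each surviving block.
#'
#' @param segment A bandpass-filtered [ppg_recording()] (typically one 10-s
#'   window).
#' @param config A [detector_config()].
#' @return Tibble of fiducial points (`sample_index`, `time_s`, `amplitude`),
#'   in strictly increasing time order.
#' @export
detect_systolic_peaks <- function(segment, config = detector_config()) {
  idx <- blocks_argmax(segment$amplitude, sampling_rate(segment), config)
  fiducial_tibble(segment, idx)
}

#' Detect pulse-wave onsets (PWB)
#'
#' Runs the same block detector on the negated waveform (so onsets become
#' maxima) and pairs each candidate trough with the nearest following
#' systolic peak. Peaks with no detected candidate fall back to the waveform
#' minimum between the preceding peak (or segment start) and the peak.
#'
#' @param segment A bandpass-filtered [ppg_recording()].
#' @param systolic_peaks Output of [detect_systolic_peaks()].
#' @param config A [detector_config()].
#' @return Tibble of onset points, one per systolic peak, each strictly
#'   before its peak.
#' @export
detect_pulse_begin <- function(segment, systolic_peaks,
                               config = detector_config()) {
  if (nrow(systolic_peaks) == 0L) return(fiducial_tibble(segment, integer(0)))
  x <- segment$amplitude
  cand <- blocks_argmax(-x, sampling_rate(segment), config)
  pk <- systolic_peaks$sample_index
  onset <- purrr::map_int(seq_along(pk), function(i) {
    lo <- if (i == 1L) 1L else pk[i - 1L]
    if (pk[i] - 1L < lo) return(NA_integer_)  # no room before a boundary peak
    hits <- cand[cand > lo & cand < pk[i]]
    if (length(hits)) {
      hits[length(hits)]  # trough closest to the upstroke
    } else {
      span <- lo:(pk[i] - 1L)
      span[which.min(x[span])]
    }
  })
  fiducial_tibble(segment, onset)
}

#' Detect diastolic peaks (PWDP)
#'
#' Second-derivative procedure: compute the second-order finite difference of
#' the waveform, smooth it with a short moving average, invert it, and take
#' the first strict local maximum after each systolic peak (and before the
#' next onset) whose height clears a small fraction of the beat's maximum.
#' Beats with no qualifying candidate are reported absent (`NA`), which is
#' the expected outcome for waveforms without a diastolic component.
#'
#' @param segment A bandpass-filtered [ppg_recording()].
#' @param systolic_peaks Output of [detect_systolic_peaks()].
#' @param config A [detector_config()].
#' @param pulse_begins Optional output of [detect_pulse_begin()]; when given,
#'   each beat's search is bounded by the next onset instead of the next peak.
#' @return Tibble with one row per systolic peak; `sample_index`, `time_s`,
#'   `amplitude` are `NA` where no diastolic peak was found.
#' @export
detect_diastolic_peaks <- function(segment, systolic_peaks,
                                   config = detector_config(),
                                   pulse_begins = NULL) {
  n_pk <- nrow(systolic_peaks)
  if (n_pk == 0L) {
    return(tibble(sample_index = integer(0), time_s = numeric(0),
                  amplitude = numeric(0)))
  }
  x <- segment$amplitude
  fs <- sampling_rate(segment)
  n <- length(x)
  d2 <- c(0, diff(x, differences = 2L), 0)
  w <- max(1L, round(config$second_derivative_smoothing_window * fs))
  inv <- -moving_average(d2, w)
  pk <- systolic_peaks$sample_index
  pb_idx <- if (is.null(pulse_begins)) integer(0) else {
    x_pb <- pulse_begins$sample_index
    x_pb[!is.na(x_pb)]
  }
  bounds <- purrr::map_int(seq_len(n_pk), function(i) {
    nxt <- pb_idx[pb_idx > pk[i]]
    if (length(nxt)) return(nxt[1])
    if (i < n_pk) pk[i + 1L] else n
  })
  idx <- purrr::map_int(seq_len(n_pk), function(i) {
    lo <- pk[i] + 1L
    hi <- bounds[i] - 1L
    if (hi - lo < 2L) return(NA_integer_)
    win <- lo:hi
    v <- inv[win]
    floor_h <- config$d2_rel_prominence * max(inv[pk[i]:bounds[i]])
    is_max <- c(FALSE, v[2:(length(v) - 1L)] > v[1:(length(v) - 2L)] &
                  v[2:(length(v) - 1L)] > v[3:length(v)], FALSE)
    ok <- which(is_max & v > floor_h & v > 0)
    if (!length(ok)) return(NA_integer_)
    win[ok[1]]  # first qualifying minimum of the 2nd derivative after PWSP
  })
  fiducial_tibble(segment, idx)
}

#' Assemble per-beat fiducial sets
#'
#' Pairs time-ordered onset, systolic-peak and diastolic-peak lists into
#' complete beats. The pulse-wave end (PWE) of beat *i* is defined as the
#' onset (PWB) of beat *i + 1*, which makes the beat partition exhaustive;
#' the final beat, having no successor, is dropped. Beats violating the
#' ordering `PWB < PWSP (< PWDP) < PWE` are dropped with a notice.
#'
#' @param pwbs,pwsps,pwdps Fiducial tibbles from the three detectors
#'   (`pwdps` may contain `NA` rows for absent diastolic peaks).
#' @return Tibble with one row per complete beat: `beat`, then
#'   `{pwb,pwsp,pwdp,pwe}_{index,time,amp}` and `next_pwsp_time` (the
#'   following beat's systolic-peak time, for the inter-beat interval).
#' @export
assemble_beats <- function(pwbs, pwsps, pwdps = NULL) {
  n <- min(nrow(pwbs), nrow(pwsps))
  if (n < 2L) {
    return(empty_beats())
  }
  i <- seq_len(n - 1L)
  pwb_t <- pwbs$time_s[i]
  pwsp_t <- pwsps$time_s[i]
  pwe_t <- pwbs$time_s[i + 1L]
  complete <- !is.na(pwb_t) & !is.na(pwsp_t) & !is.na(pwe_t)
  ordered <- complete & pwb_t < pwsp_t & pwsp_t < pwe_t
  n_bad <- sum(complete & !ordered)
  if (n_bad > 0) {
    inform(sprintf("Dropping %d beat(s): fiducial ordering violated.", n_bad))
  }
  keep <- which(ordered)
  if (!length(keep)) return(empty_beats())

  pwdp_i <- rep(NA_integer_, n - 1L)
  pwdp_t <- rep(NA_real_, n - 1L)
  pwdp_a <- rep(NA_real_, n - 1L)
  if (!is.null(pwdps) && nrow(pwdps) > 0L) {
    j <- seq_len(min(n - 1L, nrow(pwdps)))
    in_beat <- !is.na(pwdps$time_s[j]) &
      pwdps$time_s[j] > pwsp_t[j] & pwdps$time_s[j] < pwe_t[j]
    in_beat[is.na(in_beat)] <- FALSE
    pwdp_i[j][in_beat] <- pwdps$sample_index[j][in_beat]
    pwdp_t[j][in_beat] <- pwdps$time_s[j][in_beat]
    pwdp_a[j][in_beat] <- pwdps$amplitude[j][in_beat]
  }
  next_pwsp <- c(pwsps$time_s, NA_real_)[i + 1L]
  tibble::new_tibble(list(
    beat = i[keep],
    pwb_index = pwbs$sample_index[i][keep], pwb_time = pwb_t[keep],
    pwb_amp = pwbs$amplitude[i][keep],
    pwsp_index = pwsps$sample_index[i][keep], pwsp_time = pwsp_t[keep],
    pwsp_amp = pwsps$amplitude[i][keep],
    pwdp_index = pwdp_i[keep], pwdp_time = pwdp_t[keep],
    pwdp_amp = pwdp_a[keep],
    pwe_index = pwbs$sample_index[i + 1L][keep], pwe_time = pwe_t[keep],
    pwe_amp = pwbs$amplitude[i + 1L][keep],
    next_pwsp_time = next_pwsp[keep]
  ), nrow = length(keep))
}

empty_beats <- function() {
  tibble(beat = integer(0),
         pwb_index = integer(0), pwb_time = numeric(0), pwb_amp = numeric(0),
         pwsp_index = integer(0), pwsp_time = numeric(0),
         pwsp_amp = numeric(0),
         pwdp_index = integer(0), pwdp_time = numeric(0),
         pwdp_amp = numeric(0),
         pwe_index = integer(0), pwe_time = numeric(0), pwe_amp = numeric(0),
         next_pwsp_time = numeric(0))
}

#' Detect and assemble all fiducials of a segment
#'
#' Convenience wrapper running [detect_systolic_peaks()],
#' [detect_pulse_begin()], [detect_diastolic_peaks()] and
#' [assemble_beats()] in sequence.
#'
#' @inheritParams detect_systolic_peaks
#' @return A beats tibble (see [assemble_beats()]).
#' @export
detect_fiducials <- function(segment, config = detector_config()) {
  pwsp <- detect_systolic_peaks(segment, config)
  pwb <- detect_pulse_begin(segment, pwsp, config)
  pwdp <- detect_diastolic_peaks(segment, pwsp, config, pulse_begins = pwb)
  assemble_beats(pwb, pwsp, pwdp)
}
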