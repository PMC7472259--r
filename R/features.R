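#' Interior angle of a triangle from its side lengths
#'
#' Law-of-cosines angle at the vertex opposite side `c`:
#' `arccos((a^2 + b^2 - c^2) / (2ab))`, in degrees. Used for the
#' systolic-peak angle, where the vertex is the peak sample and the other two
#' vertices are its immediately adjacent samples.
#'
#' @param a,b Sides adjacent to the vertex.
#' @param c Side opposite the vertex.
#' @return Angle in degrees, in `(0, 180]`.
#' @export
#' @examples
#' triangle_angle(3, 4, 5)  # 90
triangle_angle <- function(a, b, c) {
  if (any(c(a, b) <= 0)) {
    abort("Degenerate triangle: a zero-length side at the vertex.",
          class = "pulsefusion_config_error")
  }
  cosv <- (a^2 + b^2 - c^2) / (2 * a * b)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

# Systolic-peak angle for each beat: the triangle joins the peak sample with
# its two adjacent samples, with time measured in sample units and amplitude
# on the (normalized) waveform. Returns NA where undefined.
pwsp_angle <- function(amplitude, pwsp_index) {
  n <- length(amplitude)
  vapply(pwsp_index, function(i) {
    if (is.na(i) || i <= 1L || i >= n) return(NA_real_)
    y0 <- amplitude[i]
    dy_prev <- amplitude[i - 1L] - y0
    dy_next <- amplitude[i + 1L] - y0
    a <- sqrt(1 + dy_next^2)
    b <- sqrt(1 + dy_prev^2)
    cc <- sqrt(4 + (amplitude[i + 1L] - amplitude[i - 1L])^2)
    triangle_angle(a, b, cc)
  }, numeric(1))
}

#' Compute the eight time-domain beat features
#'
#' Per-beat values, averaged across beats:
#' * `f1` -- Euclidean distance PWSP-PWDP in the (time, amplitude) plane;
#' * `f2` -- distance PWDP-PWE (amplitude position of the diastolic limb);
#' * `f3` -- systolic-peak angle (degrees), from the adjacent-sample triangle;
#' * `f4` -- distance PWSP-PWB (pulse-wave amplitude);
#' * `f5` -- systolic phase duration, `PWSP - PWB` (s);
#' * `f6` -- diastolic phase duration, `PWE - PWSP` (s);
#' * `f7` -- systolic-to-diastolic propagation time, `PWDP - PWSP` (s);
#' * `f8` -- inter-beat interval, next `PWSP - PWSP` (s).
#'
#' Distances mix seconds with normalized amplitude, so amplitudes should be
#' min-max scaled per segment before detection/assembly (the pipeline default;
#' see [compute_segment_features()]). Beats lacking a diastolic peak
#' contribute to `f4`, `f5`, `f6`, `f8` but not to `f1`, `f2`, `f7`; `f3`
#' requires the waveform (`amplitude`) for the adjacent samples.
#'
#' @param beats A beats tibble from [assemble_beats()].
#' @param amplitude Optional waveform vector (normalized), indexed by the
#'   beats' sample indices, used for the `f3` adjacent-sample triangle.
#' @return A one-row tibble `f1 ... f8`, `n_beats_used`.
#' @export
compute_time_features <- function(beats, amplitude = NULL) {
  if (nrow(beats) == 0L) {
    abort("No complete beats to compute features from.",
          class = "pulsefusion_config_error")
  }
  d2d <- function(t1, a1, t2, a2) sqrt((t1 - t2)^2 + (a1 - a2)^2)
  f1 <- d2d(beats$pwsp_time, beats$pwsp_amp, beats$pwdp_time, beats$pwdp_amp)
  f2 <- d2d(beats$pwdp_time, beats$pwdp_amp, beats$pwe_time, beats$pwe_amp)
  f4 <- d2d(beats$pwsp_time, beats$pwsp_amp, beats$pwb_time, beats$pwb_amp)
  f5 <- beats$pwsp_time - beats$pwb_time
  f6 <- beats$pwe_time - beats$pwsp_time
  f7 <- beats$pwdp_time - beats$pwsp_time
  f8 <- beats$next_pwsp_time - beats$pwsp_time
  f3 <- if (is.null(amplitude)) rep(NA_real_, nrow(beats)) else {
    pwsp_angle(amplitude, beats$pwsp_index)
  }
  m <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  tibble::new_tibble(
    list(f1 = m(f1), f2 = m(f2), f3 = m(f3), f4 = m(f4),
         f5 = m(f5), f6 = m(f6), f7 = m(f7), f8 = m(f8),
         n_beats_used = nrow(beats)),
    nrow = 1L)
}

#' Base frequency from heart rate
#'
#' The fundamental (first harmonic) frequency of the beat train: heart rate
#' in beats per minute divided by 60. A 96-bpm heart rate gives a 1.6-Hz
#' base, so the second harmonic sits at 3.2 Hz.
#'
#' @param heart_rate Beats per minute (> 0).
#' @return Frequency in Hz.
#' @export
compute_base_frequency <- function(heart_rate) {
  check_number(heart_rate, "heart_rate", lower = 0)
  heart_rate / 60
}

#' Heart rate from systolic-peak times
#'
#' `60 / median(inter-peak interval)`; the median makes the estimate robust
#' to a single missed or spurious beat.
#'
#' @param pwsp_times Systolic-peak times in seconds (>= 2), or a beats tibble
#'   from [assemble_beats()].
#' @return Heart rate in beats per minute.
#' @export
estimate_heart_rate <- function(pwsp_times) {
  if (is.data.frame(pwsp_times)) pwsp_times <- pwsp_times$pwsp_time
  if (length(pwsp_times) < 2L) {
    abort("Heart-rate estimation needs at least 2 systolic peaks.",
          class = "pulsefusion_config_error")
  }
  60 / median(diff(pwsp_times))
}

#' Harmonic amplitudes C1--C10
#'
#' Removes the segment mean, takes the discrete Fourier transform, and
#' normalizes the amplitude spectrum as `2 |X_k| / N` so a unit-amplitude
#' sinusoid at an exact bin has amplitude 1. `C_n` is the amplitude at the
#' bin nearest `n * base_frequency` (nearest-bin selection, no interpolation;
#' a 10-s window gives 0.1-Hz resolution). Harmonics at or beyond the Nyquist
#' frequency are reported as 0 with a warning. No taper is applied by
#' default; a Hann window is available for off-bin tones.
#'
#' @param segment A [ppg_recording()] window.
#' @param base_frequency Fundamental frequency, Hz.
#' @param n_harmonics Number of harmonics (default 10).
#' @param window Expected window duration in seconds (default 10); the
#'   segment must have exactly `window * sampling_rate` samples. Use `NULL`
#'   to accept any length.
#' @param taper `"none"` (default) or `"hann"`.
#' @return One-row tibble: `base_frequency`, `c1 ... c10`.
#' @export
#' @examples
#' t <- seq(0, 10 - 1 / 25, by = 1 / 25)
#' seg <- ppg_recording(cos(2 * pi * 1.6 * t), 25)
#' compute_harmonics(seg, base_frequency = 1.6)  # c1 = 1
compute_harmonics <- function(segment, base_frequency, n_harmonics = 10,
                              window = 10, taper = c("none", "hann")) {
  taper <- match.arg(taper)
  check_number(base_frequency, "base_frequency", lower = 0)
  fs <- sampling_rate(segment)
  n <- nrow(segment)
  if (!is.null(window) && n != round(window * fs)) {
    abort(sprintf("Segment has %d samples; expected %d (%g s at %g Hz).",
                  n, round(window * fs), window, fs),
          class = "pulsefusion_config_error")
  }
  x <- segment$amplitude - mean(segment$amplitude)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    x <- x * w / mean(w)
  }
  amp <- 2 * Mod(fft(x)) / n
  freqs <- (seq_len(n) - 1) * fs / n
  nyquist <- fs / 2
  cn <- vapply(seq_len(n_harmonics), function(k) {
    f <- k * base_frequency
    if (f >= nyquist) return(NA_real_)
    amp[which.min(abs(freqs[seq_len(floor(n / 2) + 1L)] - f))]
  }, numeric(1))
  if (anyNA(cn)) {
    warn(sprintf("%d harmonic(s) at/beyond Nyquist set to 0.", sum(is.na(cn))),
         class = "pulsefusion_nyquist_warning")
    cn[is.na(cn)] <- 0
  }
  tibble::new_tibble(
    c(list(base_frequency = base_frequency),
      setNames(as.list(cn), paste0("c", seq_len(n_harmonics)))),
    nrow = 1L)
}

# Min-max scale a waveform to [0, 1]; constant input stays at 0.
minmax_scale <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' All 18 PPG features of one segment
#'
#' Runs the full per-segment pipeline: amplitude normalization, fiducial
#' detection and beat assembly, time-feature averaging, heart-rate
#' estimation, and harmonic extraction. Amplitude normalization (default
#' per-segment min-max scaling to `[0, 1]`) makes the mixed-unit distances
#' `f1`, `f2`, `f4` and the harmonic amplitudes device-gain-invariant.
#'
#' A segment is invalid (`valid = FALSE`, features `NA`) when fewer than one
#' complete beat or fewer than two systolic peaks are found.
#'
#' @param segment A bandpass-filtered [ppg_recording()] window.
#' @param config A [detector_config()].
#' @param normalization `"minmax"` (default), `"zscore"`, or `"none"`.
#' @param window Expected window duration in seconds (passed to
#'   [compute_harmonics()]); `NULL` to accept any length.
#' @return One-row tibble: `valid`, `n_beats_used`, `heart_rate_bpm`,
#'   `f1 ... f8`, `base_frequency`, `c1 ... c10`.
#' @export
compute_segment_features <- function(segment, config = detector_config(),
                                     normalization = c("minmax", "zscore",
                                                       "none"),
                                     window = 10) {
  normalization <- match.arg(normalization)
  x <- segment$amplitude
  norm_amp <- switch(normalization,
                     minmax = minmax_scale(x),
                     zscore = if (sd(x) > 0) (x - mean(x)) / sd(x)
                              else rep(0, length(x)),
                     none = x)
  norm_seg <- replace_amplitude(segment, norm_amp)
  invalid <- function() {
    tibble::new_tibble(
      c(list(valid = FALSE, n_beats_used = 0L, heart_rate_bpm = NA_real_),
        setNames(as.list(rep(NA_real_, 8)), paste0("f", 1:8)),
        list(base_frequency = NA_real_),
        setNames(as.list(rep(NA_real_, 10)), paste0("c", 1:10))),
      nrow = 1L)
  }
  pwsp <- detect_systolic_peaks(norm_seg, config)
  if (nrow(pwsp) < 2L) return(invalid())
  pwb <- detect_pulse_begin(norm_seg, pwsp, config)
  pwdp <- detect_diastolic_peaks(norm_seg, pwsp, config, pulse_begins = pwb)
  beats <- assemble_beats(pwb, pwsp, pwdp)
  if (nrow(beats) == 0L) return(invalid())
  tf <- compute_time_features(beats, amplitude = norm_seg$amplitude)
  hr <- estimate_heart_rate(pwsp$time_s)
  harm <- compute_harmonics(norm_seg, compute_base_frequency(hr),
                            window = window)
  tibble::new_tibble(
    c(list(valid = TRUE, n_beats_used = tf$n_beats_used,
           heart_rate_bpm = hr),
      as.list(tf[, paste0("f", 1:8)]),
      as.list(harm)),
    nrow = 1L)
}

#' Per-segment features of a whole recording
#'
#' Preprocesses a raw recording (zero-phase bandpass, then PMAF denoising on
#' the full trace), segments it into sliding windows, and computes the 18
#' PPG features for every window.
#'
#' @param recording A raw [ppg_recording()].
#' @param window,hop Sliding-window parameters, seconds.
#' @param config A [detector_config()].
#' @param band Bandpass corner frequencies, Hz.
#' @param pmaf_k Periods averaged by the PMAF (`NULL` skips denoising).
#' @param normalization Passed to [compute_segment_features()].
#' @return Tibble with `segment_index`, `start_s` and the
#'   [compute_segment_features()] columns, one row per window.
#' @export
extract_ppg_features <- function(recording, window = 10, hop = 1,
                                 config = detector_config(),
                                 band = c(0.5, 8), pmaf_k = 3,
                                 normalization = "minmax") {
  rec <- bandpass_filter(recording, band[1], band[2])
  if (!is.null(pmaf_k)) {
    rec <- pmaf_denoise(rec, k = pmaf_k)
  }
  segs <- segment_sliding_windows(rec, window = window, hop = hop)
  n_nyquist <- 0L
  feats <- withCallingHandlers(
    purrr::map(seq_len(nrow(segs)), function(i) {
      compute_segment_features(get_segment(rec, segs[i, ]), config = config,
                               normalization = normalization, window = window)
    }),
    pulsefusion_nyquist_warning = function(w) {
      n_nyquist <<- n_nyquist + 1L
      invokeRestart("muffleWarning")
    }
  )
  if (n_nyquist > 0L) {
    inform(sprintf(
      "%d/%d segments had harmonics at/beyond Nyquist set to 0.",
      n_nyquist, nrow(segs)))
  }
  dplyr::bind_cols(segs[, c("segment_index", "start_s")],
                   dplyr::bind_rows(feats))
}
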