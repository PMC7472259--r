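test_that("triangle angle follows the law of cosines", {
  expect_equal(triangle_angle(3, 4, 5), 90)
  # Collinear points: straight angle.
  expect_equal(triangle_angle(1, 1, 2), 180)
  expect_equal(triangle_angle(1, 1, sqrt(2)), 90)
  expect_error(triangle_angle(0, 4, 5), class = "pulsefusion_config_error")
})

test_that("time features match direct arithmetic on hand-built fiducials", {
  point <- function(i, t, a) {
    tibble::tibble(sample_index = i, time_s = t, amplitude = a)
  }
  # Two consecutive beats; features are read off the first.
  pwb <- point(c(1L, 26L), c(1.00, 2.00), c(0.0, 0.0))
  pwsp <- point(c(6L, 31L), c(1.20, 2.20), c(1.0, 1.0))
  pwdp <- point(c(13L, 38L), c(1.50, 2.50), c(0.4, 0.4))
  beats <- assemble_beats(pwb, pwsp, pwdp)
  expect_equal(nrow(beats), 1)
  tf <- compute_time_features(beats)
  expect_equal(tf$f5, 0.20)
  expect_equal(tf$f6, 0.80)
  expect_equal(tf$f7, 0.30)
  expect_equal(tf$f8, 1.00)
  expect_equal(tf$f1, sqrt(0.30^2 + 0.60^2), tolerance = 1e-10)
  expect_equal(tf$f2, sqrt(0.50^2 + 0.40^2), tolerance = 1e-10)
  expect_equal(tf$f4, sqrt(0.20^2 + 1.0^2), tolerance = 1e-10)
  expect_equal(tf$n_beats_used, 1)
})

test_that("f3 is the adjacent-sample angle on the normalized waveform", {
  # A peak whose neighbours drop by exactly 1 normalized unit on each side
  # forms a right angle (two unit-slope flanks).
  amp <- c(0, 1, 0, 0.5)
  beats <- tibble::tibble(
    beat = 1L, pwb_index = 1L, pwb_time = 0, pwb_amp = 0,
    pwsp_index = 2L, pwsp_time = 0.04, pwsp_amp = 1,
    pwdp_index = NA_integer_, pwdp_time = NA_real_, pwdp_amp = NA_real_,
    pwe_index = 4L, pwe_time = 0.12, pwe_amp = 0.5,
    next_pwsp_time = NA_real_)
  tf <- compute_time_features(beats, amplitude = amp)
  expect_equal(tf$f3, 90)
  # Collinear neighbours (flat apex) give 180 degrees.
  tf180 <- compute_time_features(
    dplyr::mutate(beats, pwsp_amp = 1),
    amplitude = c(1, 1, 1, 0.5))
  expect_equal(tf180$f3, 180)
})

test_that("base frequency is heart rate over 60", {
  expect_equal(compute_base_frequency(96), 1.6)
  expect_equal(compute_base_frequency(60), 1.0)
  expect_equal(compute_base_frequency(72), 1.2)
  expect_error(compute_base_frequency(0), class = "pulsefusion_config_error")
})

test_that("heart rate is 60 over the median inter-peak interval", {
  expect_equal(estimate_heart_rate(0:9), 60)
  expect_equal(estimate_heart_rate(seq(0, 10, by = 0.625)), 96)
  expect_equal(estimate_heart_rate(c(0, 0.9, 1.9, 3.0)), 60)  # median 1.0 s
  expect_error(estimate_heart_rate(1), class = "pulsefusion_config_error")
})

test_that("harmonic amplitudes are exact for exact-bin tones", {
  fs <- 25
  t <- (0:(10 * fs - 1)) / fs
  one_tone <- ppg_recording(cos(2 * pi * 1.6 * t), fs)
  h1 <- compute_harmonics(one_tone, base_frequency = 1.6, n_harmonics = 7)
  expect_equal(h1$c1, 1.0, tolerance = 1e-10)
  expect_true(all(as.numeric(h1[paste0("c", 2:7)]) < 1e-10))

  two_tone <- ppg_recording(cos(2 * pi * 1.6 * t) +
                              0.3 * cos(2 * pi * 3.2 * t), fs)
  h2 <- compute_harmonics(two_tone, base_frequency = 1.6, n_harmonics = 7)
  expect_equal(h2$c1, 1.0, tolerance = 1e-10)
  expect_equal(h2$c2, 0.3, tolerance = 1e-10)

  expect_error(compute_harmonics(ppg_recording(t[1:100], fs), 1.6),
               class = "pulsefusion_config_error")
  expect_warning(compute_harmonics(one_tone, base_frequency = 1.6,
                                   n_harmonics = 10, window = 10),
                 class = "pulsefusion_nyquist_warning")
})

test_that("harmonics of a beat train match a sinusoid-regression oracle", {
  cr <- clean_recording(duration = 10, heart_rate = 96)
  seg <- cr$recording
  f0 <- 1.6
  h <- compute_harmonics(seg, base_frequency = f0, n_harmonics = 7,
                         window = 10)
  orc <- oracle_harmonic_fit(seg$amplitude, 25, f0, n_harmonics = 7)
  got <- as.numeric(h[paste0("c", 1:7)])
  keep <- orc > 1e-3  # relative comparison only where the tone is present
  expect_true(all(abs(got[keep] - orc[keep]) / orc[keep] < 0.02))
})

test_that("harmonic spectrum is phase-blind and obeys a Parseval bound", {
  fs <- 25
  cr <- clean_recording(duration = 10, heart_rate = 60)
  x <- cr$recording$amplitude
  h <- compute_harmonics(cr$recording, 1.0, window = 10)
  shifted <- ppg_recording(c(x[26:length(x)], x[1:25]), fs)  # one whole beat
  h2 <- compute_harmonics(shifted, 1.0, window = 10)
  expect_lt(max(abs(as.numeric(h[paste0("c", 1:10)]) -
                      as.numeric(h2[paste0("c", 1:10)]))), 1e-6)

  xc <- x - mean(x)
  power <- mean(xc^2)
  amps <- 2 * Mod(fft(xc)) / length(xc)
  expect_lte(sum((amps[2:(length(xc) / 2)])^2), 2 * power * 2)
})

test_that("scaling the signal scales harmonics but not normalized distances", {
  cr <- clean_recording(duration = 12, heart_rate = 60)
  rec <- bandpass_filter(cr$recording)
  seg <- get_segment(rec, segment_sliding_windows(rec)[1, ])
  seg_scaled <- ppg_recording(5 * seg$amplitude, 25)

  h <- compute_harmonics(seg, 1.0, window = 10)
  hs <- compute_harmonics(seg_scaled, 1.0, window = 10)
  expect_equal(as.numeric(hs[paste0("c", 1:10)]),
               5 * as.numeric(h[paste0("c", 1:10)]), tolerance = 1e-9)

  # Min-max normalization makes the fused per-segment features gain-invariant.
  f <- compute_segment_features(seg)
  fsc <- compute_segment_features(replace_amplitude(seg, 5 * seg$amplitude))
  expect_equal(as.numeric(f[paste0("f", 1:8)]),
               as.numeric(fsc[paste0("f", 1:8)]), tolerance = 1e-9)
  expect_equal(as.numeric(f[paste0("c", 1:10)]),
               as.numeric(fsc[paste0("c", 1:10)]), tolerance = 1e-9)
})

test_that("per-segment features are consistent with the generator", {
  cr <- clean_recording(duration = 12, heart_rate = 60)
  rec <- bandpass_filter(cr$recording)
  seg <- get_segment(rec, segment_sliding_windows(rec)[1, ])
  f <- compute_segment_features(seg)
  expect_true(f$valid)
  expect_equal(f$f8, 1.00, tolerance = 0.04)
  expect_equal(f$base_frequency, 1.0, tolerance = 0.05)
  expect_lt(abs(f$f5 + f$f6 - f$f8), 0.05)  # phases partition the beat

  zero <- ppg_recording(rep(0, 250), 25)
  expect_false(compute_segment_features(zero)$valid)
})

test_that("segment features are local: slice equals standalone computation", {
  cfg <- ppg_sim_config(duration = 40, heart_rate = 70, noise_sd = 0.03,
                        hr_jitter_sd = 1, seed = 5)
  rec <- bandpass_filter(simulate_ppg(cfg))
  segs <- segment_sliding_windows(rec)
  k <- 7
  seg <- get_segment(rec, segs[k, ])
  direct <- compute_segment_features(seg)
  standalone <- compute_segment_features(
    ppg_recording(seg$amplitude, 25, start_time = seg$time_s[1]))
  expect_equal(as.data.frame(direct), as.data.frame(standalone))
})
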