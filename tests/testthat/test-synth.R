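test_that("simulated recordings have the configured length and periodicity", {
  rec <- simulate_ppg(ppg_sim_config(duration = 300, sampling_rate = 25,
                                     heart_rate = 72))
  expect_equal(nrow(rec), 7500)
  expect_equal(sampling_rate(rec), 25)

  # Noise-free 60 bpm, 30 s: exactly 30 systolic maxima spaced 1.000 s apart.
  clean <- simulate_ppg(ppg_sim_config(duration = 30, heart_rate = 60,
                                       noise_sd = 0, hr_jitter_sd = 0,
                                       baseline_wander_amplitude = 0))
  x <- clean$amplitude
  n <- length(x)
  locmax <- which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                      x[2:(n - 1)] >= x[3:n], FALSE))
  thr <- 0.9 * max(x)
  peaks <- locmax[x[locmax] > thr]
  expect_length(peaks, 30)
  gaps <- diff(clean$time_s[peaks])
  expect_true(all(abs(gaps - 1) < 1e-9))
})

test_that("per-beat secondary maximum matches the dense-grid template oracle", {
  ratio <- 0.4; delay <- 0.3; sw <- 0.07; dw <- 0.1
  orc <- oracle_template_extrema(1, ratio, delay, sw, dw)
  expect_false(is.na(orc$secondary_tau))

  cr <- clean_recording(duration = 10, heart_rate = 60, ratio = ratio,
                        delay = delay, sw = sw, dw = dw, fs = 250)
  x <- cr$recording$amplitude
  t <- cr$recording$time_s
  n <- length(x)
  locmax <- which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                      x[2:(n - 1)] >= x[3:n], FALSE))
  # One mid-recording beat: primary at ~4.5 s, its secondary follows.
  prim <- locmax[which.min(abs(t[locmax] - 4.5))]
  seconds <- locmax[locmax > prim & t[locmax] < t[prim] + 0.8]
  expect_true(length(seconds) >= 1)
  sec <- seconds[1]
  expect_lt(abs((t[sec] - t[prim]) - orc$secondary_tau), 0.01)
  expect_lt(abs(x[sec] - orc$secondary_y), 0.02)
  # Secondary amplitude is ~ratio x systolic, up to component overlap.
  expect_lt(abs(x[sec] / x[prim] - ratio), 0.1)
})

test_that("invalid simulation configs name the offending field", {
  expect_error(ppg_sim_config(duration = -1), "duration",
               class = "pulsefusion_config_error")
  expect_error(ppg_sim_config(diastolic_ratio = 1), "diastolic_ratio",
               class = "pulsefusion_config_error")
  expect_error(ppg_sim_config(heart_rate = 60, systolic_diastolic_delay = 1.2),
               "systolic_diastolic_delay",
               class = "pulsefusion_config_error")
})

test_that("GSR panel generator honours degenerate and correlated settings", {
  loc <- gsr_baseline_location()
  # scale = 0: the panel equals the location values exactly.
  p0 <- simulate_gsr_panel(gsr_params(loc, scale = 0 * loc), seed = 1)
  expect_equal(p0$median_ohm, rep(loc, each = 2), ignore_attr = TRUE)
  expect_equal(p0$channel, canonical_gsr_channels())

  # Perfect bilateral correlation: left values equal right values.
  p1 <- simulate_gsr_panel(
    gsr_params(loc, scale = 0.2 * loc, bilateral_correlation = 1), seed = 2)
  left <- p1$median_ohm[p1$side == "left"]
  right <- p1$median_ohm[p1$side == "right"]
  expect_equal(left, right)

  expect_error(gsr_params(loc, scale = -loc),
               class = "pulsefusion_config_error")
})

test_that("GSR channel draws are centred on their location", {
  loc <- gsr_baseline_location()
  params <- gsr_params(loc, scale = 0.2 * loc, bilateral_correlation = 0.5)
  draws <- vapply(seq_len(2000), function(i) {
    simulate_gsr_panel(params, seed = 10000 + i)$median_ohm[1]
  }, numeric(1))
  se <- 0.2 * loc[["LU9"]] / sqrt(length(draws))
  expect_lt(abs(mean(draws) - loc[["LU9"]]), 3 * se)
})

test_that("cohorts are sized, labeled, and reproducible from the seed", {
  cfg <- cohort_config(n_wiry = 5, n_control = 3, duration = 20, seed = 7)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort), 8)
  expect_equal(sum(cohort$label == "wiry"), 5)
  expect_equal(anyDuplicated(cohort$subject_id), 0)
  expect_equal(nrow(cohort$ppg[[1]]), 20 * 25)
  expect_equal(nrow(cohort$gsr[[1]]), 24)

  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort$ppg, cohort2$ppg)
  expect_identical(cohort$gsr, cohort2$gsr)

  expect_error(cohort_config(n_wiry = 1, n_control = 0),
               class = "pulsefusion_config_error")
})

test_that("default group parameterization lowers the wiry second harmonic", {
  cohort <- simulate_cohort(cohort_config(n_wiry = 6, n_control = 6,
                                          duration = 30, seed = 11))
  feats <- suppressMessages(extract_cohort_features(cohort))
  c2 <- feats |>
    dplyr::filter(valid) |>
    dplyr::group_by(subject_id, label) |>
    dplyr::summarise(c2 = mean(c2), .groups = "drop")
  expect_lt(mean(c2$c2[c2$label == "wiry"]),
            mean(c2$c2[c2$label == "non_wiry"]))
})
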