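# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: extrema come from dense-grid scans of the
# closed-form two-Gaussian beat shape, and harmonic amplitudes from a
# least-squares sinusoid fit.

# Dense-grid extrema of one beat of the synthetic template, relative to the
# systolic peak time. Returns the primary maximum and (if any) the secondary
# local maximum after it.
oracle_template_extrema <- function(amp, ratio, delay, sw, dw,
                                    span = c(-0.5, 1), step = 1e-4) {
  tau <- seq(span[1], span[2], by = step)
  y <- amp * (exp(-tau^2 / (2 * sw^2)) +
                ratio * exp(-(tau - delay)^2 / (2 * dw^2)))
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
              FALSE)
  peaks <- which(is_max)
  ord <- peaks[order(y[peaks], decreasing = TRUE)]
  list(
    primary_tau = tau[ord[1]], primary_y = y[ord[1]],
    secondary_tau = if (length(ord) > 1) tau[ord[2]] else NA_real_,
    secondary_y = if (length(ord) > 1) y[ord[2]] else NA_real_
  )
}

# Least-squares amplitude of sinusoids at n * f0 (regression on cos + sin),
# an FFT-free route to the harmonic amplitudes.
oracle_harmonic_fit <- function(x, fs, f0, n_harmonics = 10) {
  t <- (seq_along(x) - 1) / fs
  vapply(seq_len(n_harmonics), function(k) {
    X <- cbind(cos(2 * pi * k * f0 * t), sin(2 * pi * k * f0 * t))
    beta <- stats::coef(stats::lm(x - mean(x) ~ X - 1))
    sqrt(sum(beta^2))
  }, numeric(1))
}

# A clean (noise-free, jitter-free) recording plus its config, for
# fiducial-oracle tests.
clean_recording <- function(duration = 10, heart_rate = 60, ratio = 0.4,
                            delay = 0.3, sw = 0.09, dw = 0.12, fs = 25) {
  cfg <- ppg_sim_config(
    duration = duration, sampling_rate = fs, heart_rate = heart_rate,
    diastolic_ratio = ratio, systolic_diastolic_delay = delay,
    systolic_width = sw, diastolic_width = dw, noise_sd = 0,
    baseline_wander_amplitude = 0, hr_jitter_sd = 0
  )
  list(config = cfg, recording = simulate_ppg(cfg))
}

# Small, quick synthetic cohort used by several model tests.
quick_cohort <- function(n_per_group = 4, duration = 40, seed = 42) {
  simulate_cohort(cohort_config(n_wiry = n_per_group,
                                n_control = n_per_group,
                                duration = duration, seed = seed))
}

quick_fcn_config <- function(...) {
  fcn_config(hidden = c(16, 16), epochs = 30, batch_size = 32, ...)
}

# Fabricated segment-feature table with gaussian features; `shift` moves the
# named columns for wiry subjects (in SD units), `subject_sd` adds a shared
# per-subject random effect.
fake_features <- function(n_per_group = 10, segments = 20, shift = c(),
                          seed = 1, subject_sd = 0.6) {
  set.seed(seed)
  cols <- feature_subset_columns("all42")
  n_sub <- 2 * n_per_group
  labels <- factor(rep(c("non_wiry", "wiry"), each = n_per_group),
                   levels = c("non_wiry", "wiry"))
  rows <- lapply(seq_len(n_sub), function(i) {
    subject_effect <- rnorm(length(cols), sd = subject_sd)
    m <- matrix(rnorm(segments * length(cols), sd = 0.4), nrow = segments,
                byrow = FALSE)
    m <- sweep(m, 2, subject_effect, "+")
    colnames(m) <- cols
    d <- tibble::as_tibble(as.data.frame(m))
    if (labels[i] == "wiry") {
      for (nm in names(shift)) d[[nm]] <- d[[nm]] + shift[[nm]]
    }
    d$subject_id <- sprintf("F%03d", i)
    d$label <- labels[i]
    d$segment_index <- seq_len(segments)
    d
  })
  dplyr::bind_rows(rows)
}
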