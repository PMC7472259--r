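#' PPG simulation configuration
#'
#' Parameters of the synthetic beat model. Each beat is the sum of a systolic
#' Gaussian component and a delayed, smaller diastolic Gaussian component;
#' the beat train is overlaid with white noise and slow sinusoidal baseline
#' wander. Gaussian bumps are used because their extrema have closed forms,
#' which keeps the generator checkable against brute-force oracles.
#'
#' @param duration Recording length, seconds.
#' @param sampling_rate Sampling rate, Hz.
#' @param heart_rate Mean heart rate, beats per minute.
#' @param systolic_amplitude Height of the systolic component, arbitrary units.
#' @param diastolic_ratio Diastolic amplitude as a fraction of systolic
#'   amplitude, in `[0, 1)`.
#' @param systolic_diastolic_delay Delay from systolic to diastolic peak,
#'   seconds; must be positive and less than the beat period.
#' @param systolic_width,diastolic_width Gaussian standard deviations of the
#'   two components, seconds.
#' @param noise_sd Standard deviation of additive white noise.
#' @param baseline_wander_amplitude,baseline_wander_frequency Amplitude and
#'   frequency (Hz) of sinusoidal baseline wander.
#' @param hr_jitter_sd Per-beat heart-rate jitter (bpm); each beat period is
#'   `60 / (heart_rate + e)` with `e ~ N(0, hr_jitter_sd)`, which makes the
#'   inter-beat interval non-degenerate.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A validated `ppg_sim_config` list.
#' @export
#' @examples
#' cfg <- ppg_sim_config(duration = 30, heart_rate = 60, noise_sd = 0)
#' rec <- simulate_ppg(cfg)
ppg_sim_config <- function(duration = 300,
                           sampling_rate = 25,
                           heart_rate = 72,
                           systolic_amplitude = 1,
                           diastolic_ratio = 0.4,
                           systolic_diastolic_delay = 0.3,
                           systolic_width = 0.09,
                           diastolic_width = 0.12,
                           noise_sd = 0,
                           baseline_wander_amplitude = 0,
                           baseline_wander_frequency = 0.25,
                           hr_jitter_sd = 0,
                           seed = NULL) {
  check_number(duration, "duration", lower = 0)
  check_number(sampling_rate, "sampling_rate", lower = 0)
  check_number(heart_rate, "heart_rate", lower = 0)
  check_number(systolic_amplitude, "systolic_amplitude", lower = 0)
  check_number(diastolic_ratio, "diastolic_ratio", lower = 0, upper = 1,
               allow_equal_lower = TRUE, allow_equal_upper = FALSE)
  period <- 60 / heart_rate
  check_number(systolic_diastolic_delay, "systolic_diastolic_delay",
               lower = 0, upper = period, allow_equal_upper = FALSE)
  check_number(systolic_width, "systolic_width", lower = 0)
  check_number(diastolic_width, "diastolic_width", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0, allow_equal_lower = TRUE)
  check_number(baseline_wander_amplitude, "baseline_wander_amplitude",
               lower = 0, allow_equal_lower = TRUE)
  check_number(baseline_wander_frequency, "baseline_wander_frequency",
               lower = 0)
  check_number(hr_jitter_sd, "hr_jitter_sd", lower = 0, allow_equal_lower = TRUE)
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         heart_rate = heart_rate, systolic_amplitude = systolic_amplitude,
         diastolic_ratio = diastolic_ratio,
         systolic_diastolic_delay = systolic_diastolic_delay,
         systolic_width = systolic_width, diastolic_width = diastolic_width,
         noise_sd = noise_sd,
         baseline_wander_amplitude = baseline_wander_amplitude,
         baseline_wander_frequency = baseline_wander_frequency,
         hr_jitter_sd = hr_jitter_sd, seed = seed),
    class = "ppg_sim_config"
  )
}

# Closed-form beat template relative to the systolic peak time.
# Exposed internally so tests can evaluate it on dense grids.
beat_template <- function(tau, config) {
  config$systolic_amplitude * (
    exp(-tau^2 / (2 * config$systolic_width^2)) +
      config$diastolic_ratio *
        exp(-(tau - config$systolic_diastolic_delay)^2 /
              (2 * config$diastolic_width^2))
  )
}

#' Simulate a PPG recording
#'
#' Generates `duration * sampling_rate` samples of a quasi-periodic pulse
#' waveform. With `noise_sd = 0`, `baseline_wander_amplitude = 0` and
#' `hr_jitter_sd = 0` the signal is exactly periodic with period
#' `60 / heart_rate` seconds and each period contains a single global maximum
#' (the systolic peak) plus, when the diastolic component is present and
#' separated, one secondary local maximum.
#'
#' @param config A [ppg_sim_config()].
#' @return A [ppg_recording()] tibble.
#' @export
simulate_ppg <- function(config) {
  if (!inherits(config, "ppg_sim_config")) {
    abort("`config` must be a `ppg_sim_config`.",
          class = "pulsefusion_config_error")
  }
  with_seed(config$seed, {
    fs <- config$sampling_rate
    n <- round(config$duration * fs)
    t <- (seq_len(n) - 1) / fs
    period <- 60 / config$heart_rate

    # Peak times: first peak at period/2; per-beat period jitter on the rate.
    # Generate enough beats to cover the window plus template tails.
    n_beats <- ceiling(config$duration / period) + 4L
    if (config$hr_jitter_sd > 0) {
      rates <- pmax(config$heart_rate +
                      rnorm(n_beats, 0, config$hr_jitter_sd),
                    config$heart_rate / 3)
      periods <- 60 / rates
    } else {
      periods <- rep(period, n_beats)
    }
    peaks <- period / 2 + c(0, cumsum(periods[-n_beats]))
    peaks <- c(peaks[1] - periods[1], peaks)  # one leading beat for edge tails

    x <- numeric(n)
    support <- 6 * max(config$systolic_width, config$diastolic_width) +
      config$systolic_diastolic_delay
    for (p in peaks) {
      if (p + support < 0 || p - support > config$duration) next
      idx <- which(t >= p - support & t <= p + support)
      x[idx] <- x[idx] + beat_template(t[idx] - p, config)
    }

    if (config$baseline_wander_amplitude > 0) {
      phase <- runif(1, 0, 2 * pi)
      x <- x + config$baseline_wander_amplitude *
        sin(2 * pi * config$baseline_wander_frequency * t + phase)
    }
    if (config$noise_sd > 0) {
      x <- x + rnorm(n, 0, config$noise_sd)
    }
    ppg_recording(x, fs)
  })
}

#' GSR group parameters
#'
#' Location/scale pairs for the 24 acupoint channels, plus the correlation
#' between the left and right channel of the same acupoint (bilateral
#' symmetry is strong in practice, so the default correlation is high).
#'
#' @param location Named numeric vector of per-acupoint location values
#'   (ohms); either 12 values (recycled to both sides) named by acupoint code,
#'   or 24 values named by channel (`<code>_left` / `<code>_right`).
#' @param scale Per-acupoint scale (ohms), same naming rules; must be >= 0.
#' @param bilateral_correlation Correlation of the latent left/right draws,
#'   in `[-1, 1]`.
#' @return A `gsr_params` list.
#' @export
gsr_params <- function(location, scale, bilateral_correlation = 0.9) {
  expand <- function(x, name) {
    if (length(x) == 12L) {
      if (is.null(names(x))) names(x) <- acupoint_codes()
      if (!setequal(names(x), acupoint_codes())) {
        abort(sprintf("`%s` must be named by the 12 acupoint codes.", name),
              class = "pulsefusion_config_error")
      }
      x <- x[acupoint_codes()]
      out <- rep(x, each = 2L)
      names(out) <- canonical_gsr_channels()
      out
    } else if (length(x) == 24L) {
      if (is.null(names(x))) names(x) <- canonical_gsr_channels()
      if (!setequal(names(x), canonical_gsr_channels())) {
        abort(sprintf("`%s` must be named by the 24 canonical channels.", name),
              class = "pulsefusion_config_error")
      }
      x[canonical_gsr_channels()]
    } else {
      abort(sprintf("`%s` must have length 12 or 24.", name),
            class = "pulsefusion_config_error")
    }
  }
  location <- expand(location, "location")
  scale <- expand(scale, "scale")
  if (any(!is.finite(location)) || any(location <= 0)) {
    abort("`location` values must be positive and finite.",
          class = "pulsefusion_config_error")
  }
  if (any(!is.finite(scale)) || any(scale < 0)) {
    abort("`scale` values must be non-negative and finite.",
          class = "pulsefusion_config_error")
  }
  check_number(bilateral_correlation, "bilateral_correlation",
               lower = -1, upper = 1, allow_equal_lower = TRUE)
  structure(list(location = location, scale = scale,
                 bilateral_correlation = bilateral_correlation),
            class = "gsr_params")
}

#' Simulate a 24-channel GSR acupoint panel
#'
#' Draws one median skin resistance per channel from per-channel normal
#' location/scale distributions. The left and right channel of the same
#' acupoint share a latent factor with the configured correlation, emulating
#' the strong bilateral symmetry of acupoint impedance.
#'
#' @param params A [gsr_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with columns `channel`, `acupoint`, `side`, `median_ohm`
#'   in canonical channel order (the 12 acupoint codes, left then right each).
#' @export
simulate_gsr_panel <- function(params, seed = NULL) {
  if (!inherits(params, "gsr_params")) {
    abort("`params` must be a `gsr_params`.",
          class = "pulsefusion_config_error")
  }
  with_seed(seed, {
    rho <- params$bilateral_correlation
    z_shared <- rnorm(12)
    z_indep <- rnorm(12)
    z_left <- z_shared
    z_right <- rho * z_shared + sqrt(max(0, 1 - rho^2)) * z_indep
    z <- as.numeric(rbind(z_left, z_right))  # canonical order: left, right per code
    value <- params$location + params$scale * z
    if (any(value <= 0)) {
      warn("Non-positive simulated resistances clamped to 1 ohm.")
      value <- pmax(value, 1)
    }
    tibble(
      channel = canonical_gsr_channels(),
      acupoint = rep(acupoint_codes(), each = 2L),
      side = rep(c("left", "right"), times = 12L),
      median_ohm = unname(value)
    )
  })
}

#' Per-group simulation parameters
#'
#' Distributions from which a subject's PPG beat-shape parameters and GSR
#' panel are drawn. `ppg_mean` / `ppg_sd` give the between-subject mean and
#' standard deviation of each [ppg_sim_config()] field being varied; fields
#' not listed use the `ppg_sim_config()` default.
#'
#' @param ppg_mean,ppg_sd Named lists of per-field between-subject means/SDs.
#' @param gsr A [gsr_params()] object.
#' @return A `group_params` list.
#' @export
group_params <- function(ppg_mean, ppg_sd, gsr) {
  stopifnot(is.list(ppg_mean), is.list(ppg_sd), inherits(gsr, "gsr_params"))
  bad <- setdiff(names(ppg_sd), names(ppg_mean))
  if (length(bad)) {
    abort(sprintf("`ppg_sd` names missing from `ppg_mean`: %s",
                  paste(bad, collapse = ", ")),
          class = "pulsefusion_config_error")
  }
  structure(list(ppg_mean = ppg_mean, ppg_sd = ppg_sd, gsr = gsr),
            class = "group_params")
}

# Baseline acupoint resistance locations (ohms), Ryodoraku-style magnitudes
# (hundreds of kilo-ohms). These are plausibility choices, not calibrated norms.
gsr_baseline_location <- function() {
  1000 * c(LU9 = 210, PC7 = 180, HT7 = 230, SI5 = 260, TE4 = 240, LI5 = 220,
           BL65 = 320, LV3 = 190, ST42 = 280, SP3 = 250, GB40 = 300, KD4 = 270)
}

#' Default group parameterizations
#'
#' The wiry group differs from the control (non-wiry) group in three ways,
#' matching the reported group-difference directions: a broader/smoother
#' systolic apex (larger systolic-peak angle and weaker relative
#' second-harmonic content), a shorter systolic-to-diastolic delay (diastolic
#' peak closer in time, longer diastolic limb), and lower skin resistance at
#' four liver/kidney-associated acupoints. Magnitudes are tuning constants of
#' the generator, not physiological claims.
#'
#' @param group `"wiry"` or `"control"`.
#' @return A [group_params()] object.
#' @export
default_group_params <- function(group = c("control", "wiry")) {
  group <- match.arg(group)
  ppg_mean <- list(
    heart_rate = 74, systolic_amplitude = 1, diastolic_ratio = 0.42,
    systolic_diastolic_delay = 0.31, systolic_width = 0.085,
    diastolic_width = 0.12, noise_sd = 0.04,
    baseline_wander_amplitude = 0.15, baseline_wander_frequency = 0.25,
    hr_jitter_sd = 1.5
  )
  ppg_sd <- list(
    heart_rate = 6, systolic_amplitude = 0.1, diastolic_ratio = 0.05,
    systolic_diastolic_delay = 0.03, systolic_width = 0.012,
    diastolic_width = 0.014
  )
  loc <- gsr_baseline_location()
  if (group == "wiry") {
    ppg_mean$systolic_width <- 0.115          # broader apex: f3 up, C2 down
    ppg_mean$systolic_diastolic_delay <- 0.255 # diastolic peak closer: f7 down, f2 up
    shifted <- c("LV3", "GB40", "KD4", "PC7", "HT7", "SP3")
    loc[shifted] <- loc[shifted] * 0.84
  }
  group_params(ppg_mean, ppg_sd,
               gsr_params(location = loc, scale = 0.18 * gsr_baseline_location(),
                          bilateral_correlation = 0.9))
}

#' Cohort configuration
#'
#' @param n_wiry,n_control Group sizes.
#' @param duration Per-subject PPG duration, seconds.
#' @param sampling_rate PPG sampling rate, Hz.
#' @param wiry,control [group_params()] for each group.
#' @param seed Master seed; per-subject sub-seeds are derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_wiry = 40, n_control = 40, duration = 300,
                          sampling_rate = 25,
                          wiry = default_group_params("wiry"),
                          control = default_group_params("control"),
                          seed = NULL) {
  check_number(n_wiry, "n_wiry", lower = 0, allow_equal_lower = TRUE)
  check_number(n_control, "n_control", lower = 0, allow_equal_lower = TRUE)
  if (n_wiry + n_control < 2) {
    abort("A cohort needs at least 2 subjects.",
          class = "pulsefusion_config_error")
  }
  check_number(duration, "duration", lower = 0)
  check_number(sampling_rate, "sampling_rate", lower = 0)
  stopifnot(inherits(wiry, "group_params"), inherits(control, "group_params"))
  structure(list(n_wiry = as.integer(n_wiry), n_control = as.integer(n_control),
                 duration = duration, sampling_rate = sampling_rate,
                 wiry = wiry, control = control, seed = seed),
            class = "cohort_config")
}

draw_subject_ppg_config <- function(gp, duration, sampling_rate, seed) {
  with_seed(seed, {
    vals <- gp$ppg_mean
    for (nm in names(gp$ppg_sd)) {
      vals[[nm]] <- vals[[nm]] + rnorm(1, 0, gp$ppg_sd[[nm]])
    }
    # Keep draws inside the physical validity region.
    vals$heart_rate <- max(vals$heart_rate, 30)
    vals$systolic_width <- max(vals$systolic_width, 0.03)
    vals$diastolic_width <- max(vals$diastolic_width, 0.03)
    vals$diastolic_ratio <- min(max(vals$diastolic_ratio, 0), 0.9)
    # The dicrotic limb sits in the first ~40% of the cycle; clamping keeps
    # the diastolic component ahead of the next pulse onset at high rates.
    vals$systolic_diastolic_delay <-
      min(max(vals$systolic_diastolic_delay, 0.12),
          0.42 * 60 / vals$heart_rate)
    do.call(ppg_sim_config,
            c(vals, list(duration = duration, sampling_rate = sampling_rate,
                         seed = sample.int(.Machine$integer.max - 1L, 1))))
  })
}

#' Simulate a labeled cohort
#'
#' Generates `n_wiry + n_control` subjects, each with a PPG recording drawn
#' from its group's beat-shape distribution, a 24-channel GSR panel, a binary
#' label and a unique id. Fully reproducible from the master seed via derived
#' per-subject sub-seeds.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `subject_id`, `label` (factor, levels
#'   `non_wiry`, `wiry`), `ppg` (list of [ppg_recording()]s), `gsr` (list of
#'   panel tibbles).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_wiry = 2, n_control = 2,
#'                                         duration = 30, seed = 1))
#' cohort
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a `cohort_config`.",
          class = "pulsefusion_config_error")
  }
  n <- config$n_wiry + config$n_control
  labels <- factor(rep(c("wiry", "non_wiry"),
                       c(config$n_wiry, config$n_control)),
                   levels = c("non_wiry", "wiry"))
  subseeds <- derive_subseeds(config$seed, 2L * n)
  rows <- purrr::map(seq_len(n), function(i) {
    gp <- if (labels[i] == "wiry") config$wiry else config$control
    sim_cfg <- draw_subject_ppg_config(gp, config$duration,
                                       config$sampling_rate,
                                       seed = subseeds[2L * i - 1L])
    rec <- simulate_ppg(sim_cfg)
    attr(rec, "subject_id") <- sprintf("S%03d", i)
    panel <- simulate_gsr_panel(gp$gsr, seed = subseeds[2L * i])
    tibble(subject_id = sprintf("S%03d", i), label = labels[i],
           ppg = list(rec), gsr = list(panel))
  })
  dplyr::bind_rows(rows)
}
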