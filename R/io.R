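#' Write / read a PPG recording as two-column CSV
#'
#' The on-disk format is `time_s, amplitude`, one row per sample. Reading
#' validates the file: finite values, strictly increasing timestamps, a
#' uniform grid (any gap beyond 0.1% of the median step is an error with the
#' offending line number), and - when a declared rate is given - agreement of
#' the inferred rate within 0.1%.
#'
#' @param recording A [ppg_recording()].
#' @param path File path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a [ppg_recording()].
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(as_tibble(recording)[, c("time_s", "amplitude")], path)
  invisible(path)
}

#' @rdname write_recording
#' @param sampling_rate Optional declared rate (Hz) to validate against.
#' @export
read_recording <- function(path, sampling_rate = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    abort(sprintf("%s: expected columns time_s, amplitude.", path),
          class = "pulsefusion_parse_error")
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$amplitude))
  if (length(bad)) {
    abort(sprintf("%s: non-finite value at line %d.", path, bad[1] + 1L),
          class = "pulsefusion_parse_error")
  }
  dt <- diff(df$time_s)
  nonmono <- which(dt <= 0)
  if (length(nonmono)) {
    abort(sprintf("%s: non-increasing timestamp at line %d.",
                  path, nonmono[1] + 2L),
          class = "pulsefusion_parse_error")
  }
  step <- median(dt)
  gap <- which(abs(dt - step) > 0.001 * step)
  if (length(gap)) {
    abort(sprintf("%s: non-uniform sampling (gap of %.4g s) at line %d.",
                  path, dt[gap[1]], gap[1] + 2L),
          class = "pulsefusion_parse_error")
  }
  rate <- 1 / step
  if (!is.null(sampling_rate) &&
      abs(rate - sampling_rate) / sampling_rate > 0.001) {
    abort(sprintf("%s: inferred rate %.4g Hz differs from declared %g Hz.",
                  path, rate, sampling_rate),
          class = "pulsefusion_parse_error")
  }
  ppg_recording(df$amplitude, rate, start_time = df$time_s[1])
}

#' Write / read raw GSR samples
#'
#' Tidy CSV with columns `acupoint_code, side, time_s, resistance_ohm`.
#'
#' @param samples Data frame of raw samples.
#' @param path File path.
#' @export
write_gsr_samples <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' @rdname write_gsr_samples
#' @export
read_gsr_samples <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("acupoint_code", "side", "resistance_ohm")
  if (!all(req %in% names(df))) {
    abort(sprintf("%s: expected columns %s.", path,
                  paste(req, collapse = ", ")),
          class = "pulsefusion_parse_error")
  }
  df
}

#' Write / read a 24-channel panel as a single-row CSV
#'
#' Columns are the canonical channels with a `_kohm` suffix; values are
#' kilo-ohms (exact conversion from the internal ohms).
#'
#' @param panel A panel tibble (`channel`, `median_ohm`, ...).
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  v <- panel_to_row(panel) / 1000
  names(v) <- paste0(sub("^gsr_", "", names(v)), "_kohm")
  readr::write_csv(as_tibble(as.data.frame(as.list(v))), path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  chans <- paste0(canonical_gsr_channels(), "_kohm")
  if (!all(chans %in% names(df))) {
    abort(sprintf("%s: missing panel columns.", path),
          class = "pulsefusion_parse_error")
  }
  tibble(channel = canonical_gsr_channels(),
         acupoint = rep(acupoint_codes(), each = 2L),
         side = rep(c("left", "right"), times = 12L),
         median_ohm = as.numeric(df[1, chans]) * 1000)
}

#' Write / read a cohort directory
#'
#' One recording CSV and one panel CSV per subject plus a JSON manifest
#' (subject id, label, file paths).
#'
#' @param cohort A cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::map(seq_len(nrow(cohort)), function(i) {
    id <- cohort$subject_id[i]
    ppg_path <- file.path(dir, paste0(id, "_ppg.csv"))
    gsr_path <- file.path(dir, paste0(id, "_gsr.csv"))
    write_recording(cohort$ppg[[i]], ppg_path)
    write_panel(cohort$gsr[[i]], gsr_path)
    list(subject_id = id, label = as.character(cohort$label[i]),
         ppg = basename(ppg_path), gsr = basename(gsr_path))
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rows <- purrr::map(manifest, function(e) {
    rec <- read_recording(file.path(dir, e$ppg))
    attr(rec, "subject_id") <- e$subject_id
    tibble(subject_id = e$subject_id,
           label = factor(e$label, levels = c("non_wiry", "wiry")),
           ppg = list(rec),
           gsr = list(read_panel(file.path(dir, e$gsr))))
  })
  dplyr::bind_rows(rows)
}

#' Pipeline configuration
#'
#' One validated document holding every knob of an end-to-end run. Unknown
#' keys are rejected so config typos fail loudly.
#'
#' @param n_wiry,n_control Synthetic cohort sizes (ignored when `cohort_dir`
#'   is given).
#' @param cohort_dir Optional directory of an existing cohort
#'   ([write_cohort()] layout); when given, ingestion replaces simulation.
#' @param duration,sampling_rate Recording parameters, seconds / Hz.
#' @param window,hop Segmentation parameters, seconds.
#' @param band Bandpass corners, Hz.
#' @param pmaf_k PMAF period count (`NULL` disables).
#' @param detector Named list of [detector_config()] overrides.
#' @param model Named list of [fcn_config()] overrides.
#' @param k_folds Cross-validation folds.
#' @param run_ablation,run_importance Whether to run those stages.
#' @param seed Master seed for the whole run.
#' @param out_dir Output directory.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_wiry = 8, n_control = 8, cohort_dir = NULL,
                            duration = 300, sampling_rate = 25,
                            window = 10, hop = 1, band = c(0.5, 8),
                            pmaf_k = 3, detector = list(), model = list(),
                            k_folds = 4, run_ablation = FALSE,
                            run_importance = TRUE, seed = 1,
                            out_dir = "pulsefusion_out") {
  cfg <- list(n_wiry = n_wiry, n_control = n_control, cohort_dir = cohort_dir,
              duration = duration, sampling_rate = sampling_rate,
              window = window, hop = hop, band = band, pmaf_k = pmaf_k,
              detector = detector, model = model, k_folds = k_folds,
              run_ablation = isTRUE(run_ablation),
              run_importance = isTRUE(run_importance),
              seed = seed, out_dir = out_dir)
  check_number(cfg$window, "window", lower = 0)
  check_number(cfg$hop, "hop", lower = 0)
  check_number(cfg$k_folds, "k_folds", lower = 2, allow_equal_lower = TRUE)
  if (length(cfg$band) != 2L || cfg$band[1] <= 0 || cfg$band[2] <= cfg$band[1]) {
    abort("`band` must be increasing positive corner frequencies.",
          class = "pulsefusion_config_error")
  }
  # Constructor calls validate the nested override lists.
  do.call(detector_config, cfg$detector)
  do.call(fcn_config, cfg$model)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path `.json`, `.yaml` or `.yml` file of [pipeline_config()] keys;
#'   unknown keys are an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("%s: unknown config keys: %s.", path,
                  paste(unknown, collapse = ", ")),
          class = "pulsefusion_config_error")
  }
  do.call(pipeline_config, raw)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate/ingest, preprocessing + feature extraction,
#' cross-validation and (optionally) ablation and importance stages, writing
#' all artifacts (`features.csv`, `folds.csv`, `metrics.json`,
#' `ablation.csv`, `importance.csv`) plus a run manifest to
#' `config$out_dir`. Reruns with the same config and seed reproduce all
#' numeric outputs. The manifest is written atomically at run end.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage \"%s\" failed: %s", name,
                    conditionMessage(e)),
            class = "pulsefusion_pipeline_error")
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 3)
    out
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) {
      read_cohort(config$cohort_dir)
    } else {
      simulate_cohort(cohort_config(
        n_wiry = config$n_wiry, n_control = config$n_control,
        duration = config$duration, sampling_rate = config$sampling_rate,
        seed = config$seed))
    }
  })

  det <- do.call(detector_config, config$detector)
  mdl <- do.call(fcn_config, c(config$model,
                               if (is.null(config$model$seed))
                                 list(seed = config$seed)))
  features <- stage("features", {
    extract_cohort_features(cohort, window = config$window, hop = config$hop,
                            config = det, band = config$band,
                            pmaf_k = config$pmaf_k)
  })
  readr::write_csv(features, file.path(config$out_dir, "features.csv"))

  cv <- stage("cv", {
    cross_validate(features, mdl, k = config$k_folds, seed = config$seed)
  })
  readr::write_csv(cv$folds, file.path(config$out_dir, "folds.csv"))

  metrics <- list(cv = as.list(glance(cv)),
                  per_fold = tidy(cv))
  if (config$run_ablation) {
    ab <- stage("ablation", {
      ablation_table(features, mdl, k = config$k_folds, seed = config$seed)
    })
    readr::write_csv(ab, file.path(config$out_dir, "ablation.csv"))
    metrics$ablation <- ab
  }
  if (config$run_importance) {
    imp <- stage("importance", feature_importance(features, seed = config$seed))
    readr::write_csv(tidy(imp), file.path(config$out_dir, "importance.csv"))
  }
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")

  manifest <- list(
    package_version = as.character(utils::packageVersion("pulsefusion")),
    config = unclass(config),
    counts = list(
      subjects = nrow(cohort),
      segments = nrow(features),
      valid_segments = sum(features$valid)
    ),
    timings_s = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  tmp <- tempfile(tmpdir = config$out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, file.path(config$out_dir, "run_manifest.json"))
  invisible(manifest)
}
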