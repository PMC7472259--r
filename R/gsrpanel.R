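#' The 12 measured acupoint codes
#'
#' Standard meridian-point identifiers of the 12 bilateral Ryodoraku
#' locations, in canonical reading order: Taiyuan (LU9), Daling (PC7),
#' Shenmen (HT7), Yanggu (SI5), Yangchi (TE4), Yangxi (LI5), Shugu (BL65),
#' Taichong (LV3), Chongyang (ST42), Taibai (SP3), Chiu Hsi (GB40),
#' Dazhong (KD4).
#'
#' @return Character vector of length 12.
#' @export
acupoint_codes <- function() {
  c("LU9", "PC7", "HT7", "SI5", "TE4", "LI5",
    "BL65", "LV3", "ST42", "SP3", "GB40", "KD4")
}

#' Canonical 24-channel layout
#'
#' Channel names in the fixed order used throughout the package (and as the
#' GSR block of the fused feature vector): each acupoint code contributes its
#' left then its right channel. The ordering is a package convention chosen
#' so feature-vector positions are stable across runs.
#'
#' @return Character vector of length 24, e.g. `"LU9_left"`, `"LU9_right"`, ...
#' @export
canonical_gsr_channels <- function() {
  as.vector(t(outer(acupoint_codes(), c("left", "right"), paste, sep = "_")))
}

#' Median of a GSR sample
#'
#' Reduces one acupoint's 5-second resistance trace to its median, the single
#' feature recorded per channel. Even-length inputs use the mean of the two
#' central order statistics. Non-positive values are physically impossible
#' for a resistance and are excluded with a warning.
#'
#' @param resistance_ohm Numeric vector of resistance samples (ohms).
#' @return The median resistance, ohms.
#' @export
#' @examples
#' gsr_median(c(100, 300, 200) * 1e3)  # 200 kOhm
gsr_median <- function(resistance_ohm) {
  if (length(resistance_ohm) == 0L) {
    abort("Empty GSR sample.", class = "pulsefusion_config_error")
  }
  bad <- !is.finite(resistance_ohm) | resistance_ohm <= 0
  if (any(bad)) {
    warn(sprintf("Excluding %d non-positive/non-finite GSR samples.", sum(bad)))
    resistance_ohm <- resistance_ohm[!bad]
    if (length(resistance_ohm) == 0L) {
      abort("No valid GSR samples left.", class = "pulsefusion_config_error")
    }
  }
  median(resistance_ohm)
}

#' Assemble a 24-channel acupoint panel from raw GSR samples
#'
#' Takes tidy raw samples (one row per time point) and reduces each channel
#' to its median, returning the panel in canonical channel order. Exactly one
#' channel per (acupoint, side) pair must be present.
#'
#' @param samples Data frame with columns `acupoint_code`, `side` (`"left"` /
#'   `"right"`) and `resistance_ohm`; a `time_s` column is allowed and
#'   ignored (the median is order-invariant).
#' @return A panel tibble: `channel`, `acupoint`, `side`, `median_ohm`,
#'   24 rows in canonical order.
#' @export
assemble_panel <- function(samples) {
  req <- c("acupoint_code", "side", "resistance_ohm")
  if (!all(req %in% names(samples))) {
    abort(sprintf("`samples` must have columns: %s.", paste(req, collapse = ", ")),
          class = "pulsefusion_parse_error")
  }
  chan <- paste(samples$acupoint_code, samples$side, sep = "_")
  unknown <- setdiff(unique(chan), canonical_gsr_channels())
  if (length(unknown)) {
    abort(sprintf("Unknown acupoint channels: %s.",
                  paste(unknown, collapse = ", ")),
          class = "pulsefusion_parse_error")
  }
  missing <- setdiff(canonical_gsr_channels(), unique(chan))
  if (length(missing)) {
    abort(sprintf("Missing acupoint channels: %s.",
                  paste(missing, collapse = ", ")),
          class = "pulsefusion_parse_error")
  }
  med <- samples |>
    dplyr::group_by(channel = paste(.data$acupoint_code, .data$side, sep = "_")) |>
    dplyr::summarise(median_ohm = gsr_median(.data$resistance_ohm),
                     .groups = "drop")
  tibble(channel = canonical_gsr_channels(),
         acupoint = rep(acupoint_codes(), each = 2L),
         side = rep(c("left", "right"), times = 12L)) |>
    dplyr::left_join(med, by = "channel")
}

#' Bilateral acupoint correlation
#'
#' Diagnostic for left/right symmetry: across subjects, the Pearson
#' correlation between the left and right channel of each acupoint. Strong
#' positive correlations are the expected pattern for same-subject bilateral
#' skin-impedance measurements.
#'
#' @param panels Data frame of stacked panels with columns `subject_id`,
#'   `acupoint`, `side`, `median_ohm` (e.g. `tidyr::unnest()`ed cohort
#'   panels), or a list of panel tibbles.
#' @return Tibble `acupoint`, `n`, `correlation`; zero-variance channels give
#'   `NA` correlation.
#' @export
bilateral_correlation <- function(panels) {
  if (is.list(panels) && !is.data.frame(panels)) {
    panels <- dplyr::bind_rows(
      purrr::imap(panels, ~ dplyr::mutate(.x, subject_id = as.character(.y))))
  }
  n_sub <- dplyr::n_distinct(panels$subject_id)
  if (n_sub < 3L) {
    abort("Bilateral correlation needs panels from at least 3 subjects.",
          class = "pulsefusion_config_error")
  }
  wide <- panels |>
    dplyr::select("subject_id", "acupoint", "side", "median_ohm") |>
    tidyr::pivot_wider(names_from = "side", values_from = "median_ohm")
  wide |>
    dplyr::group_by(.data$acupoint) |>
    dplyr::summarise(
      n = dplyr::n(),
      correlation = if (sd(.data$left) == 0 || sd(.data$right) == 0) {
        NA_real_
      } else {
        cor(.data$left, .data$right)
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$acupoint, acupoint_codes()))
}

# One panel tibble -> named numeric vector in canonical order (gsr_ prefix).
panel_to_row <- function(panel) {
  v <- setNames(panel$median_ohm, panel$channel)[canonical_gsr_channels()]
  if (any(is.na(v))) {
    abort("Panel is missing canonical channels.",
          class = "pulsefusion_parse_error")
  }
  setNames(v, paste0("gsr_", canonical_gsr_channels()))
}
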