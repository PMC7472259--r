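#' Plot a PPG recording
#'
#' @param object A [ppg_recording()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ppg_recording <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
}

#' Overlay detected fiducials on a segment
#'
#' @param segment A [ppg_recording()] window.
#' @param beats A beats tibble from [assemble_beats()] /
#'   [detect_fiducials()].
#' @return A ggplot with the waveform and the PWB / PWSP / PWDP points.
#' @export
plot_fiducials <- function(segment, beats) {
  pts <- dplyr::bind_rows(
    tibble(point = "PWB", time_s = beats$pwb_time, amplitude = beats$pwb_amp),
    tibble(point = "PWSP", time_s = beats$pwsp_time,
           amplitude = beats$pwsp_amp),
    tibble(point = "PWDP", time_s = beats$pwdp_time,
           amplitude = beats$pwdp_amp)
  ) |>
    dplyr::filter(!is.na(.data$time_s))
  autoplot(segment) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(colour = .data$point), size = 2) +
    ggplot2::labs(colour = NULL)
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("segment_accuracy", "subject_accuracy"),
                              names_to = "level", values_to = "accuracy")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$fold), .data$accuracy,
                                     fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold", y = "accuracy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a feature-importance report
#'
#' @param object An `importance_report`.
#' @param top_n Number of top-ranked features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_report <- function(object, top_n = 15, ...) {
  d <- utils::head(tidy(object), top_n)
  ggplot2::ggplot(d, ggplot2::aes(.data$weight,
                                  stats::reorder(.data$feature,
                                                 .data$weight))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance weight", y = NULL) +
    ggplot2::theme_minimal()
}
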