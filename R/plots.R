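#' Bland-Altman plot
#'
#' Differences against pair means, with the bias line and the 1.96 SD limits
#' of agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  d <- tibble::tibble(
    mean = attr(object, "means"),
    diff = attr(object, "differences")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_lower, object$loa_upper),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Mean of pair", y = "Difference (pred - meas)",
      title = sprintf(
        "Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
        object$bias, object$loa_lower, object$loa_upper
      )
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of within-subject correlations
#'
#' One tile per summary x component cell for each entity, colored by r_ws;
#' significant cells (p < 0.05) are outlined.
#'
#' @param result A `cohort_result` ([build_cohort_result()]).
#' @param type Entity type to display.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(result, type = c("landmark", "segment", "joint")) {
  type <- match.arg(type)
  d <- result$within |>
    dplyr::filter(.data$entity_type == type) |>
    dplyr::mutate(cell = paste(.data$summary, .data$component, sep = "_"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$entity, fill = .data$r_ws)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dplyr::filter(d, !is.na(.data$p) & .data$p < 0.05),
      fill = NA, color = "black", linewidth = 0.4
    ) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = type, fill = "r_ws") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a stroke's wrist speed and detected forward swing
#'
#' @param record A preprocessed [stroke_record()].
#' @param window Optional phase window ([extract_forward_swing()] output);
#'   detected on the fly when omitted.
#' @param wrist Wrist landmark id.
#' @return A ggplot object.
#' @export
plot_forward_swing <- function(record, window = NULL, wrist = 16L) {
  if (is.null(window)) window <- extract_forward_swing(record, wrist = wrist)
  rate <- series_rate(record$series)
  vel <- landmark_velocities(record$series)
  d <- vel[vel$landmark == wrist, c("frame", "speed")]
  d$time <- d$frame / rate
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$speed)) +
    ggplot2::annotate("rect",
      xmin = window$start_frame / rate, xmax = window$end_frame / rate,
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "steelblue"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = record$impact_frame / rate, linetype = "dashed") +
    ggplot2::labs(
      x = "Time (s)", y = "Wrist resultant speed (m/s)",
      title = sprintf(
        "Forward swing: frames %d-%d (%.0f ms)",
        window$start_frame, window$end_frame, window$duration_ms
      )
    ) +
    ggplot2::theme_minimal()
}
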