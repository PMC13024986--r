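#' Plot longitudinal wound-area trajectories
#'
#' One line per wound, area against study day — the visual counterpart of
#' serial 3D scan measurements. Useful for spotting the typical pattern of
#' rapid early decline followed by a plateau, and for flagging wounds that
#' grew between scans.
#'
#' @param observations Data frame with `patient_id`, `location`, `day`,
#'   `area_cm2`.
#' @param log_area Plot the area axis on a log10 scale (default `TRUE`,
#'   which renders exponential healing as straight lines).
#' @return A ggplot object.
#' @export
plot_healing_trajectories <- function(observations, log_area = TRUE) {
  check_columns(observations, c("patient_id", "location", "day", "area_cm2"))
  p <- ggplot(observations,
              aes(x = .data$day, y = .data$area_cm2,
                  group = interaction(.data$patient_id, .data$location),
                  colour = .data$patient_id)) +
    geom_line(alpha = 0.7) +
    geom_point(size = 1) +
    labs(x = "study day", y = expression("wound area (" * cm^2 * ")"),
         colour = "patient") +
    theme_minimal()
  if (log_area) p <- p + scale_y_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.wound_series <- function(object, ...) {
  plot_healing_trajectories(object$observations, ...) +
    labs(title = sprintf("%s / %s", object$baseline$patient_id,
                         object$baseline$location)) +
    theme(legend.position = "none")
}

#' @exportS3Method ggplot2::autoplot
autoplot.cohort_table <- function(object, ...) {
  tab <- tidy(object)
  has_mech <- "mechanism" %in% names(tab)
  p <- ggplot(tab, aes(x = .data$a0_cm2, y = .data$percent_reduction)) +
    labs(x = expression("baseline area " * A[0] * " (" * cm^2 * ")"),
         y = "percent area reduction (%)") +
    scale_x_log10() +
    theme_minimal()
  if (has_mech) {
    p + geom_point(aes(colour = .data$mechanism), size = 2)
  } else {
    p + geom_point(size = 2)
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.synthetic_series <- function(object, ...) {
  df <- extract_series_areas(object)
  ggplot(df, aes(x = .data$day)) +
    geom_line(aes(y = .data$true_area_cm2), linetype = 2) +
    geom_point(aes(y = .data$measured_area_cm2)) +
    labs(x = "scan day", y = expression("wound area (" * cm^2 * ")"),
         title = "prescribed (dashed) vs pipeline-measured areas") +
    theme_minimal()
}
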