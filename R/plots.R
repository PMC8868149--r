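#' Mean concentration-time profiles by compartment
#'
#' Cohort mean with an SD ribbon per compartment over the whole observation
#' span, on the absolute clock.
#'
#' @param profiles tibble from [build_cohort_profiles()].
#' @param mic optional horizontal reference line at the MIC.
#' @return a ggplot object.
#' @export
plot_cohort_profiles <- function(profiles, mic = NULL) {
  agg <- profiles |>
    dplyr::group_by(.data$compartment, .data$time) |>
    dplyr::summarise(mean = mean(.data$conc), sd = stats::sd(.data$conc),
                     .groups = "drop")
  gg <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$time, y = .data$mean,
                                          colour = .data$compartment,
                                          fill = .data$compartment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Free concentration (µg/mL)",
                  colour = "Compartment", fill = "Compartment") +
    ggplot2::theme_minimal()
  if (!is.null(mic)) {
    gg <- gg + ggplot2::geom_hline(yintercept = mic, linetype = "dashed")
  }
  gg
}
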