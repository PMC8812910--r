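#' Plot ROI average waveforms
#'
#' Grand-average ERP traces per ending category, facetted over the 3 x 3
#' ROI grid (areas as rows, lateralisation as columns). Negative is plotted
#' upward, following ERP convention.
#'
#' @param object A `roi_waveforms` tibble.
#' @param categories Optional subset of categories to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roi_waveforms <- function(object, categories = NULL, ...) {
  d <- object
  if (!is.null(categories)) d <- d[d$category %in% categories, , drop = FALSE]
  d <- dplyr::summarise(
    dplyr::group_by(d, .data$category, .data$area, .data$lateralisation,
                    .data$time_ms),
    amp = mean(.data$amp), .groups = "drop"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$amp,
                                  colour = .data$category)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(
      factor(area, c("frontal", "central", "parietal")) ~
        factor(lateralisation, c("left", "middle", "right"))
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV, negative up)",
                  colour = "ending") +
    ggplot2::theme_minimal()
}

#' Plot an ANOVA table as effect sizes
#'
#' Classical eta-squared per model term, shaded by significance at the 0.05
#' level.
#'
#' @param object An `rm_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rm_anova <- function(object, ...) {
  tab <- object$table
  tab$significant <- tab$p.value < 0.05
  ggplot2::ggplot(tab, ggplot2::aes(.data$eta_sq,
                                    stats::reorder(.data$term, .data$eta_sq),
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(eta^2), y = NULL, fill = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' Difference waves between two ending categories
#'
#' Convenience helper returning deviant-minus-standard ROI difference
#' waveforms (grand-averaged over subjects and block groups).
#'
#' @param waves A `roi_waveforms` tibble.
#' @param standard,deviant Category labels.
#' @return A tibble: `roi`, `area`, `lateralisation`, `time_ms`, `diff_amp`.
#' @export
difference_waves <- function(waves, standard = "standard",
                             deviant = "phys_deviant") {
  d <- waves[waves$category %in% c(standard, deviant), , drop = FALSE]
  avg <- dplyr::summarise(
    dplyr::group_by(d, .data$category, .data$roi, .data$area,
                    .data$lateralisation, .data$time_ms),
    amp = mean(.data$amp), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(avg, names_from = "category",
                             values_from = "amp")
  wide$diff_amp <- wide[[deviant]] - wide[[standard]]
  wide[, c("roi", "area", "lateralisation", "time_ms", "diff_amp")]
}
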