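#' Plot a spectrum as magnitude and phase panels
#'
#' Magnitude in dB (or linear on a log axis) over log frequency, with the
#' unwrapped phase in cycles below — the standard presentation of
#' middle-ear frequency responses.
#'
#' @param object An [me_spectrum] (possibly stacking several spectra).
#' @param ... Unused.
#' @return A ggplot object (faceted magnitude/phase).
#' @method autoplot me_spectrum
#' @export
autoplot.me_spectrum <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(
      frequency_hz = object$frequency_hz,
      value = magnitude_db(pmax(object$magnitude, 1e-300)),
      panel = "magnitude (dB)",
      target_label = object$target_label,
      specimen_id = object$specimen_id
    ),
    tibble::tibble(
      frequency_hz = object$frequency_hz,
      value = object$phase_cycles,
      panel = "phase (cycles)",
      target_label = object$target_label,
      specimen_id = object$specimen_id
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$frequency_hz, y = .data$value,
    colour = .data$target_label,
    group = interaction(.data$target_label, .data$specimen_id)
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL, colour = "target") +
    ggplot2::theme_minimal()
}

#' @export
plot.me_spectrum <- function(x, ...) print(autoplot.me_spectrum(x, ...))

#' Plot an umbo-to-stapes transfer function with lever reference lines
#'
#' Magnitude of a transfer function over log frequency, with horizontal
#' reference lines at candidate reciprocal lever ratios. Both a nominal
#' 1/2 line and the anatomical reciprocal are drawn for elephant-style
#' comparisons; neither is asserted by the plot.
#'
#' @param tf An [me_spectrum] transfer function (e.g. TF_US).
#' @param lever_ratios Numeric vector of lever ratios whose reciprocals to
#'   draw as dashed reference lines (default `c(2, 2.8)`).
#' @return A ggplot object.
#' @export
plot_transfer_function <- function(tf, lever_ratios = c(2, 2.8)) {
  refs <- tibble::tibble(
    ratio = lever_ratios,
    reciprocal = 1 / lever_ratios,
    label = paste0("1/", lever_ratios)
  )
  ggplot2::ggplot(tf, ggplot2::aes(x = .data$frequency_hz, y = .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      data = refs,
      ggplot2::aes(yintercept = .data$reciprocal),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "frequency (Hz)", y = "|TF|",
      title = tf$target_label[1]
    ) +
    ggplot2::theme_minimal()
}

#' Plot group-delay estimates by band and target
#'
#' Corrected group delays per specimen with group means overlaid.
#'
#' @param estimates Output of [estimate_group_delays()].
#' @return A ggplot object.
#' @export
plot_group_delays <- function(estimates) {
  ggplot2::ggplot(estimates, ggplot2::aes(
    x = .data$band, y = .data$corrected_gd_us, colour = .data$group
  )) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::stat_summary(
      fun = mean, geom = "crossbar", width = 0.3,
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = "band", y = "corrected group delay (µs)") +
    ggplot2::theme_minimal()
}
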