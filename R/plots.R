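#' Plot a simulated trajectory
#'
#' Glucose and insulin time courses in stacked panels, with meal impulse
#' times marked.
#'
#' @param object A `cgm_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgm_trajectory <- function(object, ...) {
  meals <- attr(object, "meals")
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time_min", "G", "I")],
    c("G", "I"),
    names_to = "variable", values_to = "value"
  )
  long$variable <- factor(long$variable,
    levels = c("G", "I"),
    labels = c("Glucose (mg/dl)", "Insulin (µU/ml)")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_line(colour = "black") +
    ggplot2::facet_wrap(~ .data$variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL)
  if (!is.null(meals) && nrow(meals)) {
    p <- p + ggplot2::geom_vline(
      data = tibble(time_min = meals$time_min),
      ggplot2::aes(xintercept = .data$time_min),
      linetype = "dotted", colour = "grey40"
    )
  }
  p
}

#' Plot a CGM record
#'
#' @param object A `cgm_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgm_series <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$time_min, .data$glucose)
  ) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.4, colour = "firebrick") +
    ggplot2::labs(x = "Time (min)", y = "Glucose (mg/dl)")
}

#' Plot a reconstructed insulin series
#'
#' The observer estimate with the initial transient (the first `3/kI`
#' minutes of each window, where the estimate has not yet converged)
#' de-emphasised.
#'
#' @param object A `cgm_observer`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgm_observer <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$time_min, .data$I_hat, alpha = !.data$in_transient)
  ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
      guide = "none") +
    ggplot2::labs(x = "Time (min)", y = "Estimated insulin (µU/ml)")
}

#' Plot a reconstructed rate of appearance
#'
#' @param object A `cgm_ra`.
#' @param truth Optional tibble with columns `time_min`, `ra` (e.g. the
#'   `trajectory` of a synthetic bundle) overlaid for comparison.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgm_ra <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$time_min, .data$ra)
  ) +
    ggplot2::geom_line(colour = "black") +
    ggplot2::labs(
      x = "Time (min)",
      y = expression(R[a] ~ "(mg" ~ dl^-1 ~ min^-1 * ")")
    )
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = as_tibble(truth)[c("time_min", "ra")],
      colour = "firebrick", linetype = "dashed"
    )
  }
  p
}

#' Plot a glucose power spectrum
#'
#' Power against period (hours, log scale), with the dominant circadian
#' peak marked.
#'
#' @param object A `cgm_spectrum`.
#' @param band_hours Band searched for the dominant peak (default 16-32 h).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgm_spectrum <- function(object, band_hours = c(16, 32), ...) {
  peak <- dominant_period(object, band_hours)
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$period_hours, .data$power)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = peak, colour = "red", size = 2,
      ggplot2::aes(.data$period_hours, .data$power)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Period (h)", y = "Power spectral density")
}

#' Plot a fitted segment
#'
#' Overlays the fitted model simulation on the CGM data, with diary meal
#' times marked.
#'
#' @param object A `cgm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cgm_fit <- function(object, ...) {
  sim <- segment_simulation(object$data, object$meals, object$params,
    dense = TRUE)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = as_tibble(object$data),
      ggplot2::aes(.data$time_min, .data$glucose),
      colour = "firebrick", size = 0.6
    ) +
    ggplot2::geom_line(
      data = as_tibble(sim),
      ggplot2::aes(.data$time_min, .data$G)
    ) +
    ggplot2::geom_vline(
      xintercept = object$meals$time_min,
      linetype = "dotted", colour = "grey40"
    ) +
    ggplot2::labs(x = "Time (min)", y = "Glucose (mg/dl)")
}
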