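#' Plot an event-triggered average
#'
#' Mean with a +/- 1 SE ribbon against peri-event time.
#'
#' @param object An [event_triggered_average()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eta
#' @export
autoplot.eta <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = t, y = mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = mean - se, ymax = mean + se),
      fill = "grey80", na.rm = TRUE
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "time from event (s)", y = object$value_col,
      title = sprintf("event-triggered average (n = %d)", object$n_events)
    )
}

#' Plot an R vs NR triggered comparison
#'
#' R events in red, NR in blue, the convention used for peri-event power
#' comparisons.
#'
#' @param object A [triggered_compare()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot triggered_compare
#' @export
autoplot.triggered_compare <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = t, y = mean, colour = kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(R = "red", NR = "blue")) +
    ggplot2::labs(x = "time from event (s)", y = "power")
}

#' Plot a GMV series
#'
#' Total gross movement value over time, with event markers if supplied.
#'
#' @param object A [gmv_series()].
#' @param events Optional `reward_events` to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gmv_series
#' @export
autoplot.gmv_series <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = t, y = total)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(
      x = "time (s)",
      y = if (isTRUE(attr(object, "normalized"))) "GMV (normalized)" else "GMV"
    )
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = events$t, colour = "red", alpha = 0.4
    )
  }
  p
}

#' Bar plot of R / NR / baseline event rates
#'
#' @param rates An [epoch_rates()] tibble (extra rows, e.g. a baseline rate,
#'   are drawn too).
#' @return A ggplot.
#' @export
plot_epoch_rates <- function(rates) {
  rates$kind <- factor(rates$kind, levels = unique(rates$kind))
  ggplot2::ggplot(rates, ggplot2::aes(x = kind, y = rate, fill = kind)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "events / min")
}
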