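#' Plot a voltage trace
#'
#' Line plot of voltage against time, optionally overlaying detected or
#' ground-truth events as points at their onsets. Long traces are thinned
#' to at most `max_points` samples for drawing (min/max within bins, so
#' spikes stay visible).
#'
#' @param trace A [voltage_trace()].
#' @param events Optional event tibble to overlay.
#' @param max_points Plotting resolution cap.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL, max_points = 20000) {
  df <- thin_trace(trace, max_points)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$voltage_uV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (µV)",
                  title = attr(trace, "condition")) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_point(
      data = events,
      ggplot2::aes(x = .data$onset_s, y = 0, colour = .data$event_class),
      inherit.aes = FALSE, shape = 17, size = 2
    ) +
      ggplot2::labs(colour = "event class")
  }
  p
}

thin_trace <- function(trace, max_points) {
  n <- nrow(trace)
  if (n <= max_points) return(as_tibble(trace)[, c("time_s", "voltage_uV")])
  bins <- ceiling(2 * n / max_points)
  grp <- (seq_len(n) - 1L) %/% bins
  v <- trace$voltage_uV
  t <- trace$time_s
  lo <- tapply(v, grp, which.min)
  hi <- tapply(v, grp, which.max)
  offs <- as.integer(names(lo))
  idx <- sort(unique(c(offs * bins + as.integer(lo), offs * bins + as.integer(hi))))
  idx <- idx[idx >= 1 & idx <= n]
  tibble(time_s = t[idx], voltage_uV = v[idx])
}

#' @rdname plot_trace
#' @param object,... Passed through from the `autoplot` generic.
#' @export
autoplot.voltage_trace <- function(object, ...) plot_trace(object, ...)

#' Plot a quartile summary table
#'
#' Per-condition median with interquartile range, one panel for the
#' per-minute rate and one for the amplitude - a compact stand-in for the
#' day-course boxplots.
#'
#' @param summary_table Output of [build_summary_table()].
#' @return A ggplot object.
#' @export
plot_summary <- function(summary_table) {
  long <- tidyr::pivot_longer(
    summary_table[, summary_columns()],
    cols = -"condition",
    names_to = c("block", "stat"),
    names_pattern = "(freq|amp)_(.*)"
  )
  wide <- tidyr::pivot_wider(long, names_from = "stat", values_from = "value")
  wide$block <- factor(wide$block, levels = c("freq", "amp"),
                       labels = c("rate (events/min)", "amplitude (µV)"))
  wide$condition <- factor(wide$condition, levels = condition_labels())
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$condition)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$iqr_lo, ymax = .data$iqr_hi),
                           width = 0.25) +
    ggplot2::geom_point(ggplot2::aes(y = .data$q2), size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$q4), shape = 4) +
    ggplot2::facet_wrap(~block, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = "point: median; bar: IQR; cross: maximum") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-minute rates across conditions
#'
#' @param per_minute_by_condition A tibble with columns `condition` and
#'   `count` (e.g. bound rows of [events_per_minute()] outputs).
#' @return A ggplot object.
#' @export
plot_rate_boxplots <- function(per_minute_by_condition) {
  df <- per_minute_by_condition
  df$condition <- factor(df$condition, levels = condition_labels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$count)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "events per minute") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
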