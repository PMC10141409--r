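#' Plot a transmission trace
#'
#' Line plot of the trace, thinned to at most `max_points` points for
#' display (min/max per bin so fast fluctuations stay visible as an
#' envelope).
#'
#' @param trace a trace tibble.
#' @param max_points maximum points drawn.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, max_points = 20000) {
  trace <- as_trace(trace)
  n <- nrow(trace)
  df <- if (n > max_points) {
    bins <- ceiling(seq_len(n) / (n / (max_points / 2)))
    trace |>
      dplyr::mutate(bin = bins) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(time = mean(.data$time),
                       lo = min(.data$value), hi = max(.data$value),
                       .groups = "drop")
  } else {
    tibble(time = trace$time, lo = trace$value, hi = trace$value)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = (.data$lo + .data$hi) / 2),
                       linewidth = 0.2, colour = "steelblue4") +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("transmission (%s)", trace_units(trace))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for ferrotrace results
#'
#' `autoplot.ferro_rms()` draws the sliding-RMS series, optionally
#' coloured by an on/off segmentation; `autoplot.ferro_pdf()` draws a
#' kernel-density PDF; `autoplot.ferro_segments()` draws the segment
#' ribbon alone.
#'
#' @param object a ferrotrace result object.
#' @param segments optional `ferro_segments` tibble to colour the RMS
#'   series by state.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot ferro_rms
#' @export
autoplot.ferro_rms <- function(object, segments = NULL, ...) {
  units <- attr(object, "units") %||% "mV"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$rms))
  if (!is.null(segments)) {
    lab <- segments$label[findInterval(object$time, segments$t_start,
                                       rightmost.closed = FALSE)]
    df <- dplyr::mutate(tibble::as_tibble(object), state = lab)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rms,
                                          colour = .data$state)) +
      ggplot2::scale_colour_manual(values = c(on = "steelblue",
                                              off = "purple3"))
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = sprintf("sliding RMS (%s)", units)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ferro_rms
#' @method autoplot ferro_pdf
#' @export
autoplot.ferro_pdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::labs(x = "value", y = "probability density") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ferro_rms
#' @method autoplot ferro_segments
#' @export
autoplot.ferro_segments <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                                    ymin = 0, ymax = 1, fill = .data$label),
                       alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(on = "steelblue", off = "purple3")) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for ferrotrace result objects
#'
#' broom-style `tidy()` and `glance()` methods returning one-row (or
#' one-row-per-component) tibbles.
#'
#' @param x a `ferro_perm` or `ferro_dwell` object.
#' @param ... ignored.
#' @return A tibble.
#' @method tidy ferro_perm
#' @export
tidy.ferro_perm <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n.permutations = x$n_permutations, exact = x$exact,
         n.a = x$group_sizes[1], n.b = x$group_sizes[2])
}

#' @rdname tidy.ferro_perm
#' @method glance ferro_perm
#' @export
glance.ferro_perm <- function(x, ...) tidy.ferro_perm(x)

#' @rdname tidy.ferro_perm
#' @method tidy ferro_dwell
#' @export
tidy.ferro_dwell <- function(x, ...) {
  tibble(state = c("on", "off"),
         n = c(length(x$dwells_on), length(x$dwells_off)),
         mean_dwell = c(x$mean_on, x$mean_off),
         n_cycles = x$n_cycles)
}

#' @rdname tidy.ferro_perm
#' @method glance ferro_dwell
#' @export
glance.ferro_dwell <- function(x, ...) {
  tibble(mean_on = x$mean_on, mean_off = x$mean_off, n_cycles = x$n_cycles)
}

#' @rdname tidy.ferro_perm
#' @method tidy ferro_trap_event
#' @export
tidy.ferro_trap_event <- function(x, ...) tibble::as_tibble(unclass(x))
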