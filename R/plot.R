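#' Plot a bifurcation branch
#'
#' Voltage against the sweep parameter, solid where the fixed point is
#' stable and dashed where it is not, with detected events (SN/TC/HB)
#' marked.
#'
#' @param object a `branch_table` from [continue_fixed_points()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.branch_table <- function(object, ...) {
  ev <- attr(object, "events")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$param, y = .data$V)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$stable,
                                    group = cumsum(!duplicated(.data$stable)))) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      labels = c(`TRUE` = "stable", `FALSE` = "unstable/saddle"),
      name = NULL) +
    ggplot2::labs(x = "bifurcation parameter", y = "V (mV)")
  if (!is.null(ev) && nrow(ev))
    p <- p +
      ggplot2::geom_point(data = ev, ggplot2::aes(x = .data$param,
                                                  y = .data$V),
                          shape = 21, size = 2.5, fill = "white") +
      ggplot2::geom_text(data = ev,
                         ggplot2::aes(x = .data$param, y = .data$V,
                                      label = .data$type),
                         vjust = -1, size = 3)
  p
}

#' Plot a simulated voltage trace
#'
#' Membrane potential over time with the applied-current schedule beneath.
#'
#' @param object a `neuron_trace` from [integrate_model()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.neuron_trace <- function(object, ...) {
  prot <- attr(object, "protocol")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$V)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "V (mV)")
  if (!is.null(prot)) {
    base <- min(object$V) - 15
    amp <- diff(range(prot$I))
    scale <- if (amp > 0) 10 / amp else 0
    seg <- tibble::tibble(
      x = prot$t_start, xend = prot$t_end,
      y = base + (prot$I - min(prot$I)) * scale)
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, xend = .data$xend,
                               y = .data$y, yend = .data$y),
      inherit.aes = FALSE, linewidth = 0.8, colour = "grey40")
  }
  p
}

#' Plot a feedback report
#'
#' Per-gate feedback weights at the operating voltage, signed: bars below
#' zero are restorative (negative feedback), above zero regenerative.
#'
#' @param object a [feedback_report()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.feedback_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gate, y = .data$weight,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "feedback weight (mS/cm²)",
                  fill = NULL,
                  subtitle = sprintf("V = %.2f mV, balance = %.4g",
                                     attr(object, "V"),
                                     attr(object, "balance")))
}
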