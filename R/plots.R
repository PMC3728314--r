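# ggplot2 methods for the result classes. Each returns a ggplot object the
# caller can restyle.

#' @export
autoplot.sis_survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$survival - 2 * .data$se),
      ymax = pmin(1, .data$survival + 2 * .data$se))) +
    ggplot2::labs(x = "time", y = "P(survival)",
                  title = "Empirical survival curve") +
    ggplot2::ylim(0, 1)
}

#' @export
autoplot.sis_infection_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$infections, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(
      x = "infection events per replicate (censored at maximum)",
      y = "replicates",
      title = "Dichotomised persistence",
      subtitle = sprintf("middle-third mass %.1f%%",
                         100 * attr(object, "dichotomy_score")))
}

#' @export
autoplot.sis_paired_experiment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$prevalence,
                                       y = .data$invasion)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$invasion - 2 * .data$invasion_se,
      ymax = .data$invasion + 2 * .data$invasion_se), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$prevalence - 2 * .data$prevalence_se,
      xmax = .data$prevalence + 2 * .data$prevalence_se), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "quasi-prevalence of seed node (transposed network)",
                  y = "quasi-invasion probability from seed node",
                  title = "Prevalence-invasion pairing") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1))
}

#' @export
autoplot.sis_relationship <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$prevalence_transpose,
                                       y = .data$invasion)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "QSD event probability (transposed network)",
                  y = "exact invasion probability",
                  title = "Exact prevalence-invasion relationship")
}

#' Draw a graphical realisation as a percolation diagram
#'
#' Time lines for each individual with cure points (crosses) and infection
#' arrows (horizontal segments); only sensible for small populations
#' (n <= ~8).
#'
#' @param object A `sis_realisation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sis_realisation <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = data.frame(x = seq_len(object$n)),
      ggplot2::aes(x = .data$x, xend = .data$x, y = 0, yend = object$t_max),
      colour = "grey40")
  if (nrow(object$arrows)) {
    p <- p + ggplot2::geom_segment(
      data = object$arrows,
      ggplot2::aes(x = .data$from, xend = .data$to, y = .data$time,
                   yend = .data$time),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick")
  }
  if (nrow(object$cures)) {
    p <- p + ggplot2::geom_point(
      data = object$cures,
      ggplot2::aes(x = .data$node, y = .data$time),
      shape = 4, size = 2)
  }
  p + ggplot2::scale_x_continuous(breaks = seq_len(object$n),
                                  labels = object$net$labels) +
    ggplot2::labs(x = "individual", y = "time",
                  title = "Graphical representation")
}
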