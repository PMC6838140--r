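#' Plot per-condition error rates
#'
#' Mirrors the task's standard behavioural figure: one bar per condition
#' (mean error rate across subjects) with per-subject points overlaid.
#'
#' @param trials A multi-subject trial tibble.
#' @param groups Optional tibble `subject, group` used to facet by group.
#' @return A ggplot object.
#' @export
plot_error_rates <- function(trials, groups = NULL) {
  er <- error_rates(trials)
  if (!is.null(groups)) {
    er <- dplyr::left_join(er, groups[, c("subject", "group")],
                           by = "subject")
  }
  p <- ggplot2::ggplot(er, ggplot2::aes(x = .data$condition,
                                        y = .data$error_rate)) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 1) +
    ggplot2::labs(x = NULL, y = "Error rate") +
    ggplot2::ylim(0, 1)
  if (!is.null(groups)) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' @describeIn tidy.gng_fit Per-subject estimates by parameter
#'   (points + population mean).
#' @param object A `gng_fit`.
#' @export
autoplot.gng_fit <- function(object, ...) {
  td <- tidy(object)
  pop <- tibble::tibble(parameter = param_names(object$spec),
                        estimate = unname(population_means(object)))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$parameter,
                                   y = .data$estimate)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = pop, colour = "red", size = 3, shape = 18) +
    ggplot2::labs(x = NULL, y = "Estimate (natural scale)",
                  title = spec_string(object$spec))
}

#' @describeIn tidy.gng_selection iBIC of every candidate per step; the
#'   accepted candidate is highlighted.
#' @param object A `gng_selection`.
#' @export
autoplot.gng_selection <- function(object, ...) {
  steps <- object$steps
  ggplot2::ggplot(steps,
                  ggplot2::aes(x = factor(.data$step), y = .data$ibic,
                               group = .data$spec, fill = .data$accepted)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single"),
                      colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$spec), angle = 90,
                       hjust = 1.05, size = 2.5,
                       position = ggplot2::position_dodge2(width = 0.9,
                                                           preserve = "single")) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey80")) +
    ggplot2::labs(x = "Selection step", y = "iBIC", fill = "Accepted")
}
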