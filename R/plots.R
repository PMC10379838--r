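# ggplot2 methods for the result types.

#' Plot a haplotype frequency table
#'
#' Stacked per-group haplotype frequency bars; with `pie = TRUE`, one pie
#' per group (the conventional map-inset display for this kind of data).
#'
#' @param object A frequency table from [frequency_table()].
#' @param pie Draw faceted pies instead of stacked bars.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hm_freq_table <- function(object, pie = FALSE, ...) {
  keys <- setdiff(names(object),
                  c("haplotype", "n", "n_resolved", "frequency"))
  dat <- as_tibble(object) %>%
    tidyr::unite("group", all_of(keys), sep = " ")
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = if (pie) "" else .data$group,
    y = .data$frequency, fill = .data$haplotype)) +
    ggplot2::geom_col(width = 1, colour = "white", linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "haplotype frequency", fill = NULL)
  if (pie) {
    p + ggplot2::coord_polar(theta = "y") +
      ggplot2::facet_wrap(~group) +
      ggplot2::theme_void()
  } else {
    p + ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}

#' Plot a power grid
#'
#' Rejection rate of the regional comparison (and the spread of
#' destination M) against founder group size.
#'
#' @param object A grid from [run_power_analysis()].
#' @param metric `"rejection_rate"` or `"m_sd"`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hm_power_grid <- function(object,
                                   metric = c("rejection_rate", "m_sd"),
                                   ...) {
  metric <- match.arg(metric)
  lab <- c(rejection_rate = "rejection rate of regional test",
           m_sd = "sd of destination M")[metric]
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$founder_size,
                                    y = .data[[metric]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "founder group size", y = lab) +
    ggplot2::theme_minimal()
  if (metric == "rejection_rate") {
    p <- p + ggplot2::geom_hline(yintercept = object$alpha[1],
                                 linetype = "dashed")
  }
  p
}
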