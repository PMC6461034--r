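#' Plot INKA results
#'
#' `autoplot()` on an [inka()] fit draws the ranked top-`top_n` INKA score
#' bar graph, faceted by sample. `plot_inka_scatter()` draws, for one
#' sample, the INKA-versus-skew scatter restricted to kinases scoring at
#' least `plot_fraction` of the top score (horizontal position indicates
#' kinase-centric versus substrate-centric evidence).
#'
#' @param object,fit An [inka()] object.
#' @param top_n Number of kinases per sample in the bar graph.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot inka
#' @export
autoplot.inka <- function(object, top_n = 20, ...) {
  dat <- object$scores |>
    filter(!is.na(.data$rank), .data$rank <= top_n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(paste(.data$kinase_symbol, .data$sample, sep = "\r"),
                       .data$inka),
    y = .data$inka, fill = .data$skew
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_x_discrete(labels = function(x) sub("\r.*$", "", x)) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "grey60",
                                  high = "navy", midpoint = 0.5,
                                  limits = c(0, 1), name = "skew") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~sample, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "INKA score") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.inka
#' @param sample Sample id; optional for single-sample fits.
#' @param plot_fraction Minimum fraction of the top INKA score shown.
#' @export
plot_inka_scatter <- function(fit, sample = NULL, plot_fraction = 0.1) {
  sample <- resolve_sample(fit, sample)
  rk <- rank_inka(fit, sample, plot_fraction = plot_fraction)
  dat <- filter(rk$ranking, .data$in_plot_set)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$skew, y = .data$inka,
                                    label = .data$kinase_symbol)) +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = "skew (0 = kinase-centric, 1 = substrate-centric)",
      y = "INKA score", title = sample
    ) +
    ggplot2::theme_minimal()
}

#' Plot impact-score curves for competing ranking methods
#'
#' Median impact score across samples per list length, with interquartile
#' ribbon, one color per method.
#'
#' @param impacts Tibble from [impact_curve()].
#' @return A ggplot object.
#' @export
plot_impact_curve <- function(impacts) {
  summ <- impacts |>
    group_by(.data$method, .data$n) |>
    summarise(
      median = median(.data$impact),
      q1 = stats::quantile(.data$impact, 0.25),
      q3 = stats::quantile(.data$impact, 0.75),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$n, color = .data$method,
                                     fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linetype = "dashed") +
    ggplot2::labs(x = "kinase activity list length",
                  y = "kinase impact score") +
    ggplot2::theme_minimal()
}
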