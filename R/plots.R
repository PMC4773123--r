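#' Plot a read or tag length distribution
#'
#' @param x a `seedmir_lengthdist` tibble from [length_distribution()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_length_distribution <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$length, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = x$length) +
    ggplot2::labs(x = "insert length (nt)", y = "proportion of library") +
    ggplot2::theme_minimal()
}

#' @rdname plot_length_distribution
#' @param object a `seedmir_lengthdist` tibble.
#' @export
autoplot.seedmir_lengthdist <- function(object, ...) {
  plot_length_distribution(object, ...)
}

#' Plot conservation rate against abundance
#'
#' Scatter of conservation rate versus log10 read count with a linear
#' trend, the diagnostic view behind the conservation-abundance
#' correlation.
#'
#' @param object a `seedmir_cor` object from
#'   [conservation_abundance_correlation()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.seedmir_cor <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conservation_rate,
                               y = .data$log10_count)) +
    ggplot2::geom_point(colour = "darkgreen") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "conservation rate (matching entries)",
                  y = "log10 read count",
                  subtitle = sprintf("Pearson r = %.3f (n = %d)",
                                     object$estimate, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot relative expression fold changes
#'
#' @param folds tibble from [ddct()].
#' @return a ggplot object (assays on the x axis, one facet per sample).
#' @export
plot_fold_changes <- function(folds) {
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$assay, y = .data$fold)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta * Delta * C[t]})) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
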