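#' Plot a sliding-window association profile
#'
#' Line plot of mean association score against window rank position: the
#' expected shape for a dual-role factor is a high plateau at the
#' up-regulated end, near-zero middle, and a moderate rise at the
#' down-regulated end.
#'
#' @param object A `window_profile` from [sliding_window_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot window_profile
#' @export
autoplot.window_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = center, y = mean_score)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "gene rank (most up-regulated first)",
                  y = sprintf("mean association score (window = %d genes)",
                              attr(object, "window"))) +
    ggplot2::theme_minimal()
}

#' Plot a two-axis anchor-gene correlation map
#'
#' Scatter of per-gene correlation with the anchor across single cells
#' (x) versus across embryos (y), coloured by quadrant cluster, with the
#' threshold lines at +/- tau.
#'
#' @param object A `correlation_map` from [cdx2_correlation_map()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot correlation_map
#' @export
autoplot.correlation_map <- function(object, ...) {
  tau <- attr(object, "tau")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = r_single_cell, y = r_embryo,
                               color = cluster)) +
    ggplot2::geom_hline(yintercept = c(-tau, tau), linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_vline(xintercept = tau, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::lims(x = c(-1, 1), y = c(-1, 1)) +
    ggplot2::labs(x = "correlation with anchor in single cells",
                  y = "correlation with anchor across embryos") +
    ggplot2::theme_minimal()
}

#' @export
plot.embryo_clust <- function(x, ...) {
  plot(x$hclust, xlab = "embryo", sub = "",
       main = "embryo expression profiles (1 - Pearson, average linkage)",
       ...)
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
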