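# ggplot2 displays for the main result types. Traces have an autoplot()
# method (see latency.R); these helpers cover the distribution-style panels.

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line geom_point
#'   geom_tile geom_vline labs facet_wrap scale_fill_gradient2 .data
NULL

#' Plot UU vs UF cosine-similarity distributions
#'
#' @param cmp An `axis_comparison`.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_axis_comparison <- function(cmp, bins = 20) {
  df <- tidyr::pivot_longer(as_tibble(cmp), c("uu", "uf"),
                            names_to = "condition", values_to = "cosine")
  ggplot(df, aes(x = .data$cosine, fill = .data$condition)) +
    geom_histogram(alpha = 0.5, position = "identity", bins = bins) +
    labs(x = "axis cosine similarity", y = "cells",
         title = sprintf("UU vs UF axis similarity (p = %.2g)",
                         attr(cmp, "p_value")))
}

#' Plot a ramp tuning curve
#'
#' @param tc Result of [tuning_curve()].
#' @return A ggplot of responses against the preferred-axis projection with
#'   the binned means overlaid.
#' @export
plot_tuning_curve <- function(tc) {
  ggplot(tc$points, aes(x = .data$projection, y = .data$response)) +
    geom_point(alpha = 0.4) +
    geom_line(data = tc$curve,
              aes(x = .data$bin_center, y = .data$mean_response),
              colour = "red") +
    labs(x = "projection on preferred axis", y = "response (Hz)")
}

#' Plot a representational similarity matrix
#'
#' @param rsa Result of [rsa_matrix()].
#' @return A ggplot heat map.
#' @export
plot_rsa <- function(rsa) {
  ggplot(rsa$tidy, aes(x = .data$category_a, y = .data$category_b,
                       fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r")
}
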