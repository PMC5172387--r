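#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a vertex-wise heritability map
#'
#' Heritability along the vertex index with FDR-significant vertices
#' highlighted — a flattened view of the surface map.
#'
#' @param object a `heritability_map`.
#' @param ... unused.
#' @method autoplot heritability_map
#' @export
autoplot.heritability_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$h2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fdr_sig), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "FDR < q") +
    ggplot2::labs(x = "vertex", y = expression(hat(h)^2),
                  title = sprintf("Heritability map (%s model)",
                                  attr(object, "model"))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an ICC map
#'
#' @param object an `icc_map`.
#' @param threshold reference line for high reproducibility (default 0.75).
#' @param ... unused.
#' @method autoplot icc_map
#' @export
autoplot.icc_map <- function(object, threshold = 0.75, ...) {
  df <- tibble::as_tibble(object)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$icc)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "vertex", y = "ICC(2,1)",
                  title = "Test-retest reliability map") +
    ggplot2::theme_minimal()
}

#' Scree plot of a shape PCA
#'
#' @param object a [pca_components()] result.
#' @param n_show leading components to show.
#' @param ... unused.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, n_show = 20, ...) {
  df <- tidy.shape_pca(object)
  df <- df[seq_len(min(n_show, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "component", y = "explained variance fraction",
                  title = "Shape PCA scree") +
    ggplot2::theme_minimal()
}

#' Heritability vs reproducibility scatter
#'
#' The concordance view: each point is a vertex, estimated heritability
#' against test-retest ICC.
#'
#' @param conc a [concordance()] result.
#' @export
plot_concordance <- function(conc) {
  ggplot2::ggplot(conc$pairs, ggplot2::aes(x = .data$icc, y = .data$h2)) +
    ggplot2::geom_point(alpha = 0.6, colour = "purple4") +
    ggplot2::labs(x = "ICC", y = expression(hat(h)^2),
                  title = sprintf("Concordance: r = %.2f, rho = %.2f",
                                  conc$pearson, conc$spearman)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
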