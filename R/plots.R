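#' Significance tile plot
#'
#' The factor-by-variable grid of Bonferroni-adjusted permutation p values,
#' tiles coloured by -log10(p) and marked when rejected.
#'
#' @param grid A significance tibble (see [significance_table()]).
#' @param alpha Level drawn on the legend caption.
#' @return A ggplot object.
#' @export
plot_significance <- function(grid, alpha = 0.05) {
  grid <- dplyr::mutate(
    grid,
    code = factor(.data$code, levels = unname(term_codes())),
    variable = factor(.data$variable, levels = variable_names())
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$variable, y = .data$code,
                                     fill = -log10(pmax(.data$p_adj, 1e-4)))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$reject, "*", "")),
                       size = 6) +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p[adj]))) +
    ggplot2::labs(x = NULL, y = NULL,
                  caption = paste0("* adjusted p < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Scree plot of an ASCA decomposition
#'
#' @param model An `asca_model`.
#' @return A ggplot object (per-component explained-variance fractions with
#'   the cumulative curve).
#' @export
plot_scree <- function(model) {
  v <- tidy(model, "variance")
  ggplot2::ggplot(v, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained_variance),
                      fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_hline(yintercept = model$threshold, linetype = 2) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "component", y = "explained variance",
                  title = paste("ASCA scree:", model$factor)) +
    ggplot2::theme_minimal()
}

#' Variable-contribution bar plot
#'
#' @param model An `asca_model`.
#' @param dims Components aggregated over (see [asca_contributions()]).
#' @return A ggplot object.
#' @export
plot_contributions <- function(model, dims = model$n_components) {
  contrib <- asca_contributions(model, dims)
  contrib$variable <- factor(contrib$variable, levels = variable_names())
  ggplot2::ggplot(contrib, ggplot2::aes(x = .data$variable,
                                        y = .data$contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "contribution (%)",
                  title = paste0("Variable contributions: ", model$factor,
                                 " (", dims, " components)")) +
    ggplot2::theme_minimal()
}

#' ASCA biplot
#'
#' Levels as points, variables as scaled arrows, on a chosen pair of
#' components.
#'
#' @param object An `asca_model`.
#' @param dims Component pair (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asca_model
#' @export
autoplot.asca_model <- function(object, dims = c(1, 2), ...) {
  bd <- biplot_data(object, dims)
  sc <- dplyr::filter(bd, .data$type == "score")
  ld <- dplyr::filter(bd, .data$type == "loading")
  ev <- round(100 * object$explained_variance[dims], 1)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = ld, ggplot2::aes(label = .data$label),
                       colour = "firebrick", vjust = -0.6, size = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = paste0("PC", dims[1], " (", ev[1], "%)"),
                  y = paste0("PC", dims[2], " (", ev[2], "%)"),
                  title = paste("ASCA biplot:", object$factor)) +
    ggplot2::theme_minimal()
}

#' Cluster plot on the first two score components
#'
#' @param object A `level_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot level_clusters
#' @export
autoplot.level_clusters <- function(object, ...) {
  sc <- object$scores
  df <- tibble::tibble(level = object$assignments$level,
                       cluster = factor(object$assignments$cluster),
                       x = sc[, 1],
                       y = if (ncol(sc) > 1) sc[, 2] else 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$level), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = paste0("k-means on ",
                                 if (!is.na(object$factor)) object$factor
                                 else "scores",
                                 " scores (k = ", object$k, ")")) +
    ggplot2::theme_minimal()
}

#' Normal QQ plot of a diagnostic
#'
#' @param object A `qq_diag` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qq_diag
#' @export
autoplot.qq_diag <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$theoretical,
                                              y = .data$sample)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::labs(title = paste0("QQ ", object$variable, " (r = ",
                                 round(object$correlation, 4), ")"),
                  x = "standard normal quantiles", y = "sample quantiles") +
    ggplot2::theme_minimal()
}
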