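#' Plot a scan result
#'
#' Per-term -log10 p scores with the experiment-wise permutation threshold.
#'
#' @param object A `qts_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qts_scan <- function(object, ...) {
  df <- object$records %>% mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$passes)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey50"),
                                 name = "passes") +
    ggplot2::labs(x = "term (ranked by score)",
                  y = expression(-log[10] ~ italic(P)),
                  title = sprintf("%s scan (experiment-wise alpha = %g)",
                                  object$stage, object$alpha_ew)) +
    ggplot2::theme_minimal()
}

#' Plot predicted effects of a fitted model
#'
#' Forest-style plot of BLUP effects with +-1 standard-error bars, faceted
#' by random-effect group.
#'
#' @param object A `qts_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qts_fit <- function(object, ...) {
  df <- object$effects
  if (!nrow(df)) abort("fit has no random effects to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$column)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$effect - .data$std_error,
                                         xmax = .data$effect + .data$std_error),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "predicted effect (trait units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a heritability partition
#'
#' Stacked single-bar view of the four category heritabilities.
#'
#' @param object A `qts_herit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qts_herit <- function(object, ...) {
  cats <- object$categories[c("h2_A", "h2_AA", "h2_AE", "h2_AAE")]
  df <- tibble(category = factor(names(cats), levels = names(cats)),
               h2 = as.numeric(cats))
  ggplot2::ggplot(df, ggplot2::aes(x = "trait", y = .data$h2, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "heritability (%)",
                  title = sprintf("h2_T = %.2f%%", object$categories["h2_T"])) +
    ggplot2::theme_minimal()
}

#' Plot the locus network
#'
#' Circular layout of the node/edge tables from [export_network()]: node
#' colour encodes the effect class, edge colour the epistasis class.
#'
#' @param network List with `nodes` and `edges` (see [export_network()]).
#' @return A ggplot.
#' @export
plot_network <- function(network) {
  nodes <- network$nodes
  if (!nrow(nodes)) abort("network has no nodes")
  nodes <- nodes %>%
    mutate(angle = 2 * pi * (row_number() - 1) / dplyr::n(),
           x = cos(.data$angle), y = sin(.data$angle))
  edges <- network$edges %>%
    left_join(select(nodes, locus_i = "locus", xi = "x", yi = "y"), by = "locus_i") %>%
    left_join(select(nodes, locus_j = "locus", xj = "x", yj = "y"), by = "locus_j")
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xi, y = .data$yi, xend = .data$xj, yend = .data$yj,
                   colour = .data$class), linewidth = 0.4)
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, shape = .data$class),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$locus), size = 2.4) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "epistasis", shape = "locus class")
}
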