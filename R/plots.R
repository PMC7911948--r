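#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a variation graph
#'
#' Schematic layout: x is the backbone coordinate (insertions offset past
#' their anchor), y separates parallel alleles. Epsilon nodes are drawn as
#' small black points, base nodes as labelled circles. Intended for the
#' small graphs one inspects by eye, not whole-genome mixtures.
#'
#' @param object A `variant_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot variant_graph
#' @export
autoplot.variant_graph <- function(object, ...) {
  ids <- object$nodes$id
  kind <- object$nodes$kind
  L <- object$reference$length
  xpos <- function(id, kind) {
    num <- function(p) as.numeric(p)
    vapply(seq_along(id), function(k) {
      i <- id[k]
      switch(kind[k],
        source = -0.8,
        sink = L + 0.8,
        epsilon = if (startsWith(i, "e:")) num(sub("^e:", "", i)) + 0.45
                  else num(sub("^ei:([0-9]+)$", "\\1", i)) + 0.75,
        base = if (startsWith(i, "b:")) num(sub("^b:([0-9]+):.*$", "\\1", i))
               else num(sub("^bi:([0-9]+)\\.([0-9]+):.*$", "\\1", i)) + 0.45 +
                 0.3 * num(sub("^bi:([0-9]+)\\.([0-9]+):.*$", "\\2", i)) /
                 (L + 1)
      )
    }, numeric(1L))
  }
  nd <- tibble(id = ids, kind = kind, label = object$nodes$label,
               x = xpos(ids, kind))
  nd <- dplyr::group_by(nd, .data$x)
  nd <- dplyr::mutate(nd, y = seq_len(dplyr::n()) - (dplyr::n() + 1) / 2)
  nd <- dplyr::ungroup(nd)
  nd$y[startsWith(nd$id, "bi:")] <- nd$y[startsWith(nd$id, "bi:")] + 1
  nd$y[startsWith(nd$id, "ei:")] <- nd$y[startsWith(nd$id, "ei:")] + 1
  ed <- graph_edges(object)
  ed$x <- nd$x[match(ed$from, nd$id)]
  ed$y <- nd$y[match(ed$from, nd$id)]
  ed$xend <- nd$x[match(ed$to, nd$id)]
  ed$yend <- nd$y[match(ed$to, nd$id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey55",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(
      data = nd[nd$kind != "base", ],
      ggplot2::aes(.data$x, .data$y), size = 1.6
    ) +
    ggplot2::geom_label(
      data = nd[nd$kind == "base", ],
      ggplot2::aes(.data$x, .data$y, label = .data$label)
    ) +
    ggplot2::labs(x = "reference position", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Study plots: explaining-pair counts, non-excluded counts, match statistics
#'
#' Companions to [run_study()]: the distribution of the number of haplotype
#' pairs explaining each mixture, the distribution of the number of distinct
#' non-excluded haplotypes (both on a square-root count scale), and the
#' per-mixture GBC likelihood against p(RMNE) on log10 axes.
#'
#' @param study A `mito_study` tibble.
#' @return A ggplot.
#' @name study-plots
NULL

#' @rdname study-plots
#' @export
plot_pair_counts <- function(study) {
  ggplot2::ggplot(study, ggplot2::aes(.data$n_explaining_pairs)) +
    ggplot2::geom_bar() +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "haplotype pairs explaining the mixture",
                  y = "mixtures (sqrt scale)")
}

#' @rdname study-plots
#' @export
plot_consistent_counts <- function(study) {
  ggplot2::ggplot(study, ggplot2::aes(.data$n_consistent)) +
    ggplot2::geom_bar() +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "distinct haplotypes not excluded",
                  y = "mixtures (sqrt scale)")
}

#' @rdname study-plots
#' @export
plot_match_stats <- function(study) {
  ggplot2::ggplot(study,
                  ggplot2::aes(.data$log10_p_rmne, .data$log10_gbc)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "log10 p(RMNE)",
                  y = "log10 GBC likelihood (one known)")
}

#' @rdname study-plots
#' @param object A `mito_study` tibble.
#' @param type One of `"pairs"`, `"consistent"`, `"stats"`.
#' @param ... Unused.
#' @method autoplot mito_study
#' @export
autoplot.mito_study <- function(object,
                                type = c("pairs", "consistent", "stats"),
                                ...) {
  switch(match.arg(type),
         pairs = plot_pair_counts(object),
         consistent = plot_consistent_counts(object),
         stats = plot_match_stats(object))
}
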