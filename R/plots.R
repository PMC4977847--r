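# ggplot2 views of the main result types.

#' @export
autoplot.weight_vector <- function(object, bridges = NULL, ...) {
  d <- tidy(object)
  d$is_bridge <- if (is.null(bridges)) FALSE else d$gene %in% bridges
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$weight,
                                  colour = .data$is_bridge)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = if (is.null(bridges)) "none" else
                                   ggplot2::guide_legend(title = "bridge")) +
    ggplot2::labs(x = "weight rank", y = "node weight",
                  title = "Iterated-matrix node weights") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.module_set <- function(object, ...) {
  d <- tibble(module = factor(object$module_id), size = object$size,
              n_bridges = lengths(object$central_bridges))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$module, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_bridges),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "module", y = "member genes",
                  title = "Modules after bridge deletion",
                  subtitle = "labels: adjacent bridge genes") +
    ggplot2::theme_minimal()
}

#' Dot plot of per-module enrichment results
#'
#' @param results Tibble from [enrich_modules()].
#' @param top_n Terms shown per module.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 5) {
  d <- results |>
    dplyr::group_by(.data$module_id) |>
    dplyr::slice_min(.data$p_adj, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$module_id),
                                  y = .data$term_id,
                                  size = .data$k / .data$n,
                                  colour = -log10(.data$p_adj))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "module", y = "GO term", size = "module fraction",
                  colour = "-log10 adj. p",
                  title = "Per-module GO enrichment") +
    ggplot2::theme_minimal()
}
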