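#' Plot GA convergence curves
#'
#' Best-so-far composite fitness per generation, one line per run. With
#' elitism the curves are monotone non-increasing.
#'
#' @param object A `ga_result` from [ga_optimize()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(
    object$convergence,
    ggplot2::aes(
      x = .data$iteration, y = .data$best_j,
      group = .data$run, colour = factor(.data$run)
    )
  ) +
    ggplot2::geom_step(alpha = 0.8) +
    ggplot2::labs(
      x = "generation", y = "best composite fitness J",
      colour = "run", title = "GA convergence"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a clustered effect matrix
#'
#' @param object An `effect_clustering` from [cluster_effects()].
#' @param ... Unused.
#' @return A ggplot tile map with axes in dendrogram leaf order; red =
#'   downregulation, green = upregulation.
#' @method autoplot effect_clustering
#' @export
autoplot.effect_clustering <- function(object, ...) {
  long <- tibble::as_tibble(as.table(object$weights), .name_repair = "minimal")
  names(long) <- c("gene_symbol", "drug_id", "weight")
  long$gene_symbol <- factor(long$gene_symbol, levels = object$gene_order)
  long$drug_id <- factor(long$drug_id, levels = object$drug_order)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$drug_id, y = .data$gene_symbol, fill = .data$weight)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "firebrick3", mid = "white", high = "forestgreen",
      limits = c(-1, 1), name = "effect"
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Drug-gene regulation effects") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot best MAE against combination size with the Pareto frontier
#'
#' @param pareto Tibble from [pareto_filter()].
#' @return A ggplot faceted by scenario; frontier points are starred.
#' @export
plot_pareto <- function(pareto) {
  ggplot2::ggplot(
    pareto,
    ggplot2::aes(x = .data$drug_count, y = .data$mae)
  ) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(
      data = dplyr::filter(pareto, .data$on_frontier),
      shape = 8, size = 4, colour = "firebrick3"
    ) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(
      x = "combination size (drugs)", y = "best MAE",
      title = "Best-fit MAE by combination size (* = Pareto frontier)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the MAE-only comparison grid
#'
#' @param grid Tibble from [compare_mae_only()].
#' @return A ggplot tile map: one cell per scenario and combination size,
#'   coloured by whether the full objective lowered, preserved or raised
#'   the best MAE relative to the MAE-only baseline.
#' @export
plot_comparison_grid <- function(grid) {
  ggplot2::ggplot(
    grid,
    ggplot2::aes(
      x = factor(.data$drug_count), y = .data$scenario,
      fill = .data$outcome
    )
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      lower = "forestgreen", equal = "grey80", higher = "firebrick3"
    )) +
    ggplot2::labs(
      x = "combination size", y = NULL,
      title = "Full objective vs MAE-only baseline"
    ) +
    ggplot2::theme_minimal()
}
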