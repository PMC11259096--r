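#' Plot per-gel network metrics by condition
#'
#' Jittered points with the group mean, one panel per metric — the
#' standard way network-complexity metrics are compared across
#' conditions.
#'
#' @param metrics tibble from [run_pipeline()]'s `metrics` element (or
#'   any table with a `condition` column and metric columns).
#' @param which character vector of metric columns to show.
#' @return A ggplot object.
#' @export
plot_network_metrics <- function(metrics,
                                 which = c("total_length_per_mm3", "n_vessels",
                                           "n_branches", "avg_branch_length_um")) {
  which <- intersect(which, names(metrics))
  long <- tidyr::pivot_longer(
    metrics, dplyr::all_of(which),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.35, width = 0.6) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 1.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot spheroid outgrowth areas and fold change over days
#'
#' @param fold_changes tibble from [spheroid_fold_changes()].
#' @return A ggplot object.
#' @export
plot_spheroid_growth <- function(fold_changes) {
  ggplot2::ggplot(
    fold_changes,
    ggplot2::aes(x = .data$day, y = .data$area_mm2, group = .data$spheroid)
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "outgrowth area (mm²)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the post-hoc comparisons of a routed analysis
#'
#' Adjusted p-values for every pairwise comparison, with the alpha line.
#'
#' @param object a [route_and_test()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.stat_routing_result <- function(object, ...) {
  ph <- tidy(object)
  if (nrow(ph) == 0) abort("The fit has no post-hoc table (posthoc = FALSE).")
  ph$pair <- paste(ph$group1, "vs", ph$group2)
  ggplot2::ggplot(ph, ggplot2::aes(x = .data$pair, y = .data$p_adj)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "adjusted p",
      subtitle = sprintf("route: %s", object$route)
    ) +
    ggplot2::theme_minimal()
}
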