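# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a permutation test result
#'
#' @param x A `perm_test` from [fda_auc_test()] or [group_auc_test()].
#' @param ... Unused.
#' @return One-row tibble with the observed AUC difference, per-group means,
#'   and the permutation p-value.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, scope = x$scope,
    group_a = x$groups[1], group_b = x$groups[2],
    mean_auc_a = x$mean_a %||% NA_real_,
    mean_auc_b = x$mean_b %||% NA_real_,
    observed_stat = x$observed_stat, p_value = x$p_value)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) {
  dplyr::mutate(tidy(x), n_permutations = x$n_permutations,
                two_sided = x$two_sided,
                n_a = as.integer(x$n[1]), n_b = as.integer(x$n[2]))
}

#' Plot metric-versus-density curves
#'
#' Global curves are drawn per subject with the group mean highlighted; pass
#' a pre-filtered single metric for a readable panel, or facet over all.
#'
#' @param object A `metric_curves` tibble (optionally joined to a `group`
#'   column).
#' @param metric Optional metric name filter.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_curves <- function(object, metric = NULL, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$node_id == "GLOBAL")
  if (!is.null(metric)) df <- df[df$metric %in% metric, ]
  has_group <- "group" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$value))
  if (has_group) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(group = .data$subject_id,
                                      colour = .data$group), alpha = 0.25) +
      ggplot2::stat_summary(ggplot2::aes(colour = .data$group),
                            fun = mean, geom = "line", linewidth = 1.1)
  } else {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                                alpha = 0.4)
  }
  p + ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "network density", y = "metric value")
}

#' Plot a permutation null distribution with the observed statistic
#'
#' @param x A `perm_test`.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(x, bins = 40) {
  df <- tibble::tibble(stat = x$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = x$observed_stat, colour = "red") +
    ggplot2::labs(x = sprintf("null AUC difference (%s)", x$metric),
                  y = "count",
                  title = sprintf("%s: observed = %.4g, p = %.4g",
                                  x$metric, x$observed_stat, x$p_value))
}

#' Plot volume-difference versus topology-difference points with the fit
#'
#' @param data Output of [group_differences()].
#' @param fit Optional matching [volume_topology_regression()] row.
#' @return A ggplot object.
#' @export
plot_volume_regression <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$volume_diff,
                                          y = .data$topo_diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "volume difference (control - patient)",
                  y = "metric AUC difference")
  if (!is.null(fit)) {
    p <- p + ggplot2::ggtitle(sprintf("%s: R² = %.3f, p = %.3g",
                                      fit$scope, fit$r_squared, fit$p_value))
  }
  p
}
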