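# Permutation inference on metric-curve AUCs, FDR-corrected regional tests,
# and hub identification.

#' Permutation-test configuration
#'
#' @param n_permutations Number of label permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed for the permutation stream.
#' @param two_sided Two-sided p-values (default TRUE).
#' @param hub_rule Hub criterion: `"permutation_2sd"` (node score exceeds
#'   mean + 2 SD of that node's permutation-ensemble scores) or
#'   `"within_network_2sd"` (node score exceeds mean + 2 SD of all node scores
#'   in the same group).
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_permutations = 1000, alpha = 0.05, seed = NULL,
                        two_sided = TRUE,
                        hub_rule = c("permutation_2sd", "within_network_2sd")) {
  if (n_permutations < 1) {
    abort("n_permutations must be positive", class = "netsweep_config_error")
  }
  if (n_permutations < 100) {
    warn("fewer than 100 permutations: p-values are unreliable")
  }
  if (!(alpha > 0 && alpha < 1)) {
    abort("alpha must be in (0, 1)", class = "netsweep_config_error")
  }
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = seed, two_sided = isTRUE(two_sided),
                 hub_rule = match.arg(hub_rule)),
            class = "perm_config")
}

.check_groups <- function(group, groups = NULL) {
  if (is.null(groups)) groups <- unique(group)
  if (length(groups) != 2) {
    abort("exactly two groups are required", class = "netsweep_group_error")
  }
  if (any(table(factor(group, levels = groups)) < 2)) {
    abort("each group needs at least 2 subjects",
          class = "netsweep_insufficient_group_error")
  }
  groups
}

# Core permutation engine on a subjects x targets AUC matrix. Returns the
# observed group-mean differences (A - B), the B x targets null matrix, and
# the permuted per-group mean matrices needed for the hub rule.
.auc_permute <- function(auc_mat, group, groups, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ia <- which(group == groups[1])
  ib <- which(group == groups[2])
  mean_a <- colMeans(auc_mat[ia, , drop = FALSE])
  mean_b <- colMeans(auc_mat[ib, , drop = FALSE])
  observed <- mean_a - mean_b
  n <- nrow(auc_mat)
  b <- cfg$n_permutations
  null_a <- matrix(NA_real_, b, ncol(auc_mat))
  null_b <- matrix(NA_real_, b, ncol(auc_mat))
  for (r in seq_len(b)) {
    pa <- sample.int(n, length(ia))
    null_a[r, ] <- colMeans(auc_mat[pa, , drop = FALSE])
    null_b[r, ] <- colMeans(auc_mat[-pa, , drop = FALSE])
  }
  list(observed = observed, mean_a = mean_a, mean_b = mean_b,
       null = null_a - null_b, perm_mean_a = null_a, perm_mean_b = null_b)
}

.perm_p <- function(observed, null, two_sided) {
  if (two_sided) {
    (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
  } else {
    (1 + sum(null >= observed)) / (length(null) + 1)
  }
}

#' FDA-style permutation test on curve AUCs
#'
#' Compares two groups on the area under a metric-versus-density curve. The
#' observed statistic is the difference of group-mean AUCs (group A minus
#' group B); the null distribution is built by randomly reassigning subjects'
#' curves to two groups of the original sizes. P-values use the
#' +1-corrected convention `p = (1 + #{|null| >= |obs|}) / (B + 1)`.
#'
#' @param curves Long tibble with columns `subject_id`, `group`, `density`,
#'   `value` holding one metric's curves for all subjects (a filtered
#'   [sweep_cohort()] result joined to group labels).
#' @param cfg A [perm_config()].
#' @param groups Optional length-2 vector fixing group order (A, B); default
#'   is first-appearance order.
#' @param metric Metric name recorded in the result.
#' @param scope Scope label recorded in the result (default "global").
#' @return A `perm_test` object; see [tidy.perm_test()].
#' @export
fda_auc_test <- function(curves, cfg = perm_config(), groups = NULL,
                         metric = NULL, scope = "global") {
  metric <- metric %||% (if ("metric" %in% names(curves))
    unique(curves$metric) else "metric")
  if (length(metric) != 1) {
    abort("curves must contain a single metric; filter first",
          class = "netsweep_config_error")
  }
  grids <- curves |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(g = paste(sort(.data$density), collapse = ","),
                     .groups = "drop")
  if (length(unique(grids$g)) != 1) {
    abort("all subjects must share one density grid",
          class = "netsweep_grid_mismatch_error")
  }
  auc <- curves |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::arrange(.data$density, .by_group = TRUE) |>
    dplyr::summarise(auc = pracma::trapz(.data$density, .data$value),
                     .groups = "drop")
  groups <- .check_groups(auc$group, groups)
  pr <- .auc_permute(matrix(auc$auc, ncol = 1), auc$group, groups, cfg)
  structure(
    list(metric = metric, scope = scope,
         observed_stat = unname(pr$observed),
         mean_a = unname(pr$mean_a), mean_b = unname(pr$mean_b),
         null_distribution = drop(pr$null),
         p_value = .perm_p(pr$observed, pr$null, cfg$two_sided),
         groups = groups, n = table(factor(auc$group, levels = groups)),
         n_permutations = cfg$n_permutations, two_sided = cfg$two_sided,
         seed = cfg$seed),
    class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> %s [%s]: AUC diff (%s - %s) = %.4g, p = %.4g (%d permutations)\n",
    x$metric, x$scope, x$groups[1], x$groups[2], x$observed_stat, x$p_value,
    x$n_permutations))
  invisible(x)
}

#' Regional (per-node) permutation tests with FDR correction
#'
#' Applies the AUC permutation comparison of [fda_auc_test()] to every node's
#' curve of one nodal metric, using a single shared permutation stream across
#' nodes, and adjusts the raw p-values with the Benjamini-Hochberg step-up
#' procedure.
#'
#' @param curves Long tibble with columns `subject_id`, `group`, `node_id`,
#'   `density`, `value` for one nodal metric.
#' @param cfg A [perm_config()].
#' @param groups Optional group order (A, B).
#' @param metric Metric name recorded in the result.
#' @return A `regional_tests` object: a tibble (`node_id`, `mean_a`, `mean_b`,
#'   `observed_stat`, `p_value`, `p_fdr`, `significant`) with the permutation
#'   ensembles of per-group mean AUCs stored in attributes `perm_mean_a` /
#'   `perm_mean_b` (used by [identify_hubs()]).
#' @export
regional_tests <- function(curves, cfg = perm_config(), groups = NULL,
                           metric = NULL) {
  metric <- metric %||% (if ("metric" %in% names(curves))
    unique(curves$metric) else "metric")
  auc <- curves |>
    dplyr::group_by(.data$subject_id, .data$group, .data$node_id) |>
    dplyr::arrange(.data$density, .by_group = TRUE) |>
    dplyr::summarise(auc = pracma::trapz(.data$density, .data$value),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(auc, names_from = "node_id", values_from = "auc")
  node_ids <- setdiff(names(wide), c("subject_id", "group"))
  amat <- as.matrix(wide[, node_ids])
  groups <- .check_groups(wide$group, groups)
  pr <- .auc_permute(amat, wide$group, groups, cfg)
  p_raw <- vapply(seq_along(node_ids), function(j) {
    .perm_p(pr$observed[j], pr$null[, j], cfg$two_sided)
  }, numeric(1))
  p_fdr <- p.adjust(p_raw, method = "BH")
  res <- tibble::tibble(
    node_id = node_ids, metric = metric,
    mean_a = unname(pr$mean_a), mean_b = unname(pr$mean_b),
    observed_stat = unname(pr$observed),
    p_value = p_raw, p_fdr = p_fdr, significant = p_fdr < cfg$alpha)
  class(res) <- c("regional_tests", class(res))
  attr(res, "perm_mean_a") <- pr$perm_mean_a
  attr(res, "perm_mean_b") <- pr$perm_mean_b
  attr(res, "groups") <- groups
  attr(res, "cfg") <- cfg
  res
}

#' Identify hub nodes from nodal centrality curves
#'
#' A node is a hub when its group-mean AUC of the criterion curve (degree or
#' betweenness) exceeds a mean + 2 SD threshold. Under the
#' `"permutation_2sd"` rule the reference distribution is that node's
#' permutation ensemble of group-mean AUCs (from [regional_tests()]); under
#' `"within_network_2sd"` it is the distribution of scores across all nodes
#' of the same group.
#'
#' @param regional A `regional_tests` result for the criterion metric.
#' @param group Which group's hubs to extract: `"a"` or `"b"` (positions in
#'   the group order used for the tests) or an explicit group label.
#' @param rule Overrides the hub rule in the `perm_config` used for
#'   `regional`.
#' @return A `hub_set` tibble: `node_id`, `score`, `threshold`, `is_hub`,
#'   with attributes `group`, `criterion`, `rule`.
#' @export
identify_hubs <- function(regional, group = "a", rule = NULL) {
  groups <- attr(regional, "groups")
  cfg <- attr(regional, "cfg")
  rule <- rule %||% cfg$hub_rule
  if (!rule %in% c("permutation_2sd", "within_network_2sd")) {
    abort("unknown hub rule", class = "netsweep_config_error")
  }
  gl <- if (group %in% c("a", "b")) groups[match(group, c("a", "b"))]
        else if (group %in% groups) group
        else abort("unknown group", class = "netsweep_group_error")
  pos <- match(gl, groups)
  score <- if (pos == 1) regional$mean_a else regional$mean_b
  if (rule == "permutation_2sd") {
    ens <- if (pos == 1) attr(regional, "perm_mean_a")
           else attr(regional, "perm_mean_b")
    mu <- colMeans(ens)
    s <- apply(ens, 2, sd)
    if (any(s == 0)) warn("zero-variance permutation ensemble for some nodes")
    threshold <- mu + 2 * s
  } else {
    s <- sd(score)
    if (s == 0) warn("zero variance across node scores; threshold equals mean")
    threshold <- rep(mean(score) + 2 * s, length(score))
  }
  res <- tibble::tibble(node_id = regional$node_id, score = score,
                        threshold = threshold, is_hub = score > threshold)
  class(res) <- c("hub_set", class(res))
  attr(res, "group") <- gl
  attr(res, "criterion") <- unique(regional$metric)
  attr(res, "rule") <- rule
  res
}

#' Group-level AUC permutation test on mean connectivity matrices
#'
#' Alternative comparison mode: one mean connectivity matrix is built per
#' group, swept, and the AUC difference of the chosen global metric is the
#' statistic; permutations reassign subjects to groups before averaging.
#' Much slower than the subject-level default (each permutation re-runs the
#' density sweep on two matrices); intended for small cohorts.
#'
#' @param matrices List of `connectivity_matrix` objects.
#' @param group Group label per subject (aligned with `matrices`).
#' @param metric One global metric name.
#' @param sweep_cfg A [sweep_config()].
#' @param cfg A [perm_config()].
#' @param groups Optional group order.
#' @return A `perm_test` object.
#' @export
group_auc_test <- function(matrices, group, metric = "clustering",
                           sweep_cfg = sweep_config(), cfg = perm_config(),
                           groups = NULL) {
  groups <- .check_groups(group, groups)
  stat <- function(assign) {
    vals <- vapply(groups, function(g) {
      mm <- Reduce(`+`, matrices[assign == g]) / sum(assign == g)
      cur <- sweep_metrics(connectivity_matrix(mm), sweep_cfg,
                           metrics = metric, subject_id = g)
      sum_auc <- curve_auc(dplyr::filter(cur, .data$metric == !!metric))
      sum_auc$auc
    }, numeric(1))
    vals[1] - vals[2]
  }
  observed <- stat(group)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  null <- vapply(seq_len(cfg$n_permutations),
                 function(i) stat(sample(group)), numeric(1))
  structure(
    list(metric = metric, scope = "global(group-level)",
         observed_stat = observed, null_distribution = null,
         p_value = .perm_p(observed, null, cfg$two_sided),
         groups = groups, n = table(factor(group, levels = groups)),
         n_permutations = cfg$n_permutations, two_sided = cfg$two_sided,
         seed = cfg$seed),
    class = "perm_test")
}
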