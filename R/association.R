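# Clinical and volumetric association analyses: Spearman correlations,
# Mann-Whitney group comparisons, lobe averaging, and volume-difference
# versus topology-difference regressions.

#' Spearman correlation between a topological and a clinical variable
#'
#' Average ranks for ties; two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Reported uncorrected.
#'
#' @param data Data frame with one row per subject.
#' @param topology,clinical Column names (strings) of the two variables.
#' @return A one-row tibble: `topology`, `clinical`, `rho`, `p_value`, `n`.
#' @export
spearman_assoc <- function(data, topology, clinical) {
  x <- data[[topology]]
  y <- data[[clinical]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("Spearman correlation needs at least 3 complete pairs",
          class = "netsweep_insufficient_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input",
          class = "netsweep_undefined_correlation_error")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  tibble::tibble(topology = topology, clinical = clinical,
                 rho = rho, p_value = p, n = n)
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' The z statistic is reported as a positive magnitude with a direction flag
#' (`"a>b"` when the first sample tends larger).
#'
#' @param values_a,values_b Numeric samples.
#' @return A one-row tibble: `u`, `z`, `direction`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n1 <- length(values_a)
  n2 <- length(values_b)
  if (n1 == 0 || n2 == 0) {
    abort("both samples must be nonempty",
          class = "netsweep_insufficient_data_error")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    abort("all values identical across both samples: test degenerate",
          class = "netsweep_degenerate_test_error")
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z_signed <- (u - n1 * n2 / 2) / sigma
  tibble::tibble(u = u, z = abs(z_signed),
                 direction = ifelse(z_signed >= 0, "a>b", "b>a"),
                 p_value = 2 * pnorm(-abs(z_signed)), n_a = n1, n_b = n2)
}

#' Average nodal values within atlas lobes
#'
#' Unweighted mean over the nodes of each lobe; computed per group when a
#' `group` column is present.
#'
#' @param nodal Data frame with `node_id`, `value`, and optionally `group`.
#' @param atlas Atlas node table.
#' @param lobe Optional lobe name (or vector) to restrict to; default all.
#' @return A tibble: (`group`,) `lobe`, `mean_value`, `n_nodes`.
#' @export
lobe_average <- function(nodal, atlas, lobe = NULL) {
  atlas <- validate_atlas(atlas)
  if (!is.null(lobe)) {
    unknown <- setdiff(lobe, atlas$lobe)
    if (length(unknown) > 0) {
      abort(paste0("lobe(s) not in atlas: ", paste(unknown, collapse = ", ")),
            class = "netsweep_lookup_error")
    }
  }
  df <- dplyr::inner_join(
    dplyr::mutate(nodal, node_id = as.integer(.data$node_id)),
    atlas[, c("node_id", "lobe")], by = "node_id")
  if (!is.null(lobe)) df <- dplyr::filter(df, .data$lobe %in% !!lobe)
  keys <- intersect(c("group", "lobe"), names(df))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     n_nodes = dplyr::n(), .groups = "drop")
}

#' Regress nodal topology differences on volume differences
#'
#' Ordinary least squares of the per-node group difference in a metric AUC on
#' the per-node group difference in mean cortical volume, over the nodes of
#' one lobe or the whole brain. Differences follow the control-minus-patient
#' convention by default (configurable upstream).
#'
#' @param data Data frame with columns `node_id`, `volume_diff`, `topo_diff`.
#' @param atlas Atlas node table.
#' @param scope A lobe name, or `"overall"` for all nodes.
#' @return A one-row tibble: `scope`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n_nodes`.
#' @export
volume_topology_regression <- function(data, atlas, scope = "overall") {
  atlas <- validate_atlas(atlas)
  df <- dplyr::inner_join(
    dplyr::mutate(data, node_id = as.integer(.data$node_id)),
    atlas[, c("node_id", "lobe")], by = "node_id")
  if (!identical(scope, "overall")) {
    if (!scope %in% atlas$lobe) {
      abort(paste0("unknown lobe: ", scope), class = "netsweep_lookup_error")
    }
    df <- dplyr::filter(df, .data$lobe == !!scope)
  }
  if (nrow(df) < 3) {
    abort("regression needs at least 3 nodes in scope",
          class = "netsweep_insufficient_data_error")
  }
  if (sd(df$volume_diff) == 0) {
    abort("zero variance in volume differences: regression degenerate",
          class = "netsweep_degenerate_regression_error")
  }
  fit <- lm(topo_diff ~ volume_diff, data = df)
  sm <- summary(fit)
  tibble::tibble(
    scope = scope,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["volume_diff", "Pr(>|t|)"],
    n_nodes = nrow(df))
}

#' Per-node group differences of volumes and metric AUCs
#'
#' Convenience builder for [volume_topology_regression()]: averages nodal
#' metric AUCs and volumes within groups and returns the per-node differences
#' `reference` minus `other` (default control minus patient).
#'
#' @param nodal_auc Tibble from [curve_auc()] on nodal curves, joined to a
#'   `group` column (one metric).
#' @param volumes Long volume tibble (`subject_id`, `node_id`, `volume`) with
#'   a `group` column.
#' @param reference Group treated as minuend (default `"control"`).
#' @param as_percent Express volume differences as percent of the reference
#'   group mean.
#' @return Tibble: `node_id`, `volume_diff`, `topo_diff`.
#' @export
group_differences <- function(nodal_auc, volumes, reference = "control",
                              as_percent = FALSE) {
  dmean <- function(df, col) {
    df |>
      dplyr::group_by(node_id = as.integer(.data$node_id), .data$group) |>
      dplyr::summarise(m = mean(.data[[col]]), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "group", values_from = "m")
  }
  va <- dmean(volumes, "volume")
  ta <- dmean(nodal_auc, "auc")
  other <- setdiff(setdiff(names(va), "node_id"), reference)
  vd <- va[[reference]] - va[[other]]
  if (as_percent) vd <- 100 * vd / va[[reference]]
  tibble::tibble(node_id = va$node_id, volume_diff = vd,
                 topo_diff = ta[[reference]][match(va$node_id, ta$node_id)] -
                   ta[[other]][match(va$node_id, ta$node_id)])
}
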