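# Density-sweep binarization and graph-theoretical indices.
#
# All metrics are computed on binary undirected graphs, as in the
# Brain Connectivity Toolbox lineage: path length averages over connected
# pairs only (component count surfaced), local clustering of degree<2 nodes
# is 0, and normalized metrics divide by the mean over degree-preserving
# (Maslov-Sneppen) rewired references.

GLOBAL_METRICS <- c("clustering", "char_path_length", "global_efficiency",
                    "local_efficiency", "modularity", "transitivity",
                    "n_components")
NORMALIZED_METRICS <- c("normalized_clustering", "normalized_path_length",
                        "small_world_index")
NODAL_METRICS <- c("degree", "betweenness", "betweenness_raw",
                   "clustering", "local_efficiency")

#' Density-sweep configuration
#'
#' @param d_min,d_max,d_step Density grid: fraction of all possible edges
#'   retained at each threshold. Defaults 0.02 to 0.2 in steps of 0.02
#'   (10 grid points).
#' @param n_random_refs Number of degree-preserving random reference graphs
#'   used for metric normalization (default 20).
#' @param rewire_iterations_per_edge Attempted double-edge swaps per edge when
#'   building each reference (default 10).
#' @param seed Optional RNG seed for reference generation.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(d_min = 0.02, d_max = 0.2, d_step = 0.02,
                         n_random_refs = 20, rewire_iterations_per_edge = 10,
                         seed = NULL) {
  if (!(d_min > 0 && d_min <= d_max && d_max < 1)) {
    abort("densities must satisfy 0 < d_min <= d_max < 1",
          class = "netsweep_config_error")
  }
  if (d_step <= 0) {
    abort("d_step must be positive", class = "netsweep_config_error")
  }
  cfg <- structure(list(d_min = d_min, d_max = d_max, d_step = d_step,
                        n_random_refs = as.integer(n_random_refs),
                        rewire_iterations_per_edge =
                          as.integer(rewire_iterations_per_edge),
                        seed = seed),
                   class = "sweep_config")
  if (length(density_grid(cfg)) < 2) {
    abort("density sweep must contain at least 2 densities",
          class = "netsweep_config_error")
  }
  if (cfg$n_random_refs < 1 || cfg$rewire_iterations_per_edge < 1) {
    abort("n_random_refs and rewire_iterations_per_edge must be positive",
          class = "netsweep_config_error")
  }
  cfg
}

#' @rdname sweep_config
#' @param cfg A `sweep_config`.
#' @return `density_grid()`: the numeric vector of sweep densities, inclusive
#'   of both endpoints.
#' @export
density_grid <- function(cfg) {
  g <- seq(cfg$d_min, cfg$d_max + cfg$d_step * 1e-8, by = cfg$d_step)
  round(g[g <= cfg$d_max + cfg$d_step * 1e-8], 10)
}

#' Binarize a weighted matrix at a target density
#'
#' Keeps the `E = round(d * N * (N - 1) / 2)` largest-weight undirected edges.
#' Ties at the cutoff are broken deterministically: descending weight, then
#' ascending `(i, j)` index pair. If fewer than `E` nonzero weights exist, all
#' nonzero edges are kept and a density-shortfall warning is raised.
#'
#' @param m Symmetric weight matrix (`connectivity_matrix` or plain matrix).
#' @param d Target density in (0, 1).
#' @return A `binary_network`: list with `adjacency` (0/1 matrix), `density`
#'   (realized), `n_edges`, `target_density`.
#' @export
threshold_to_density <- function(m, d) {
  .threshold_take(.threshold_prep(m), d)
}

# sort the upper-triangle weights once; density cuts are prefixes of this
# order, which also makes edge-set nestedness across the sweep structural
.threshold_prep <- function(m) {
  m <- unclass(as.matrix(m))
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  ord <- order(-w, ut[, 1], ut[, 2])
  list(n = n, ut = ut, ord = ord, n_nonzero = sum(w > 0))
}

.threshold_take <- function(prep, d) {
  if (!(d > 0 && d < 1)) {
    abort("density must be in (0, 1)", class = "netsweep_config_error")
  }
  n_pairs <- prep$n * (prep$n - 1) / 2
  e_target <- round(d * n_pairs)
  if (e_target == 0) {
    abort(sprintf("density %.4g yields zero edges for %d nodes", d, prep$n),
          class = "netsweep_empty_network_error")
  }
  if (prep$n_nonzero < e_target) {
    warn(sprintf(
      "density shortfall: %d nonzero weights available for %d requested edges",
      prep$n_nonzero, e_target))
    e_take <- prep$n_nonzero
  } else {
    e_take <- e_target
  }
  keep <- prep$ord[seq_len(e_take)]
  adj <- matrix(0L, prep$n, prep$n)
  adj[prep$ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, density = e_take / n_pairs,
                 n_edges = e_take, target_density = d),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.4f)\n",
              nrow(x$adjacency), x$n_edges, x$density))
  invisible(x)
}

.as_graph <- function(bn) {
  igraph::graph_from_adjacency_matrix(bn$adjacency, mode = "undirected")
}

.nodal_clustering <- function(g) {
  igraph::transitivity(g, type = "localundirected", isolates = "zero")
}

.char_path_length <- function(g) {
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (length(d) == 0) return(NA_real_)
  mean(d)
}

# Latora-Marchiori local efficiency in the induced-neighborhood-subgraph
# convention of the Brain Connectivity Toolbox: for each node, the global
# efficiency of the subgraph induced by its neighbors (the node removed);
# nodes with fewer than 2 neighbors score 0. igraph's local_efficiency()
# instead measures neighbor distances in the full graph minus the node, so
# it is not used here.
.local_efficiency <- function(g) {
  vapply(igraph::V(g), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) < 2) return(0)
    igraph::global_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
}

# Deterministic single-node-move refinement of a community assignment:
# repeatedly move each node (fixed order) to the candidate community with
# the largest strictly positive modularity gain until no move improves Q.
.refine_membership <- function(nb_list, deg, m, mem, max_passes = 20L) {
  n <- length(nb_list)
  n_slot <- n + 1L # one spare slot = "fresh singleton community"
  comm_deg <- numeric(n_slot)
  for (v in seq_len(n)) comm_deg[mem[v]] <- comm_deg[mem[v]] + deg[v]
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (v in seq_len(n)) {
      nb <- nb_list[[v]]
      if (length(nb) == 0) next
      a <- mem[v]
      k_counts <- tabulate(mem[nb], nbins = n_slot)
      empty <- which(comm_deg == 0)[1]
      cands <- c(unique(mem[nb]), empty)
      cands <- cands[!is.na(cands) & cands != a]
      if (length(cands) == 0) next
      dq <- (k_counts[cands] - k_counts[a]) / m +
        deg[v] * (comm_deg[a] - comm_deg[cands] - deg[v]) / (2 * m^2)
      j <- which.max(dq)
      if (dq[j] > 1e-12) {
        b <- cands[j]
        comm_deg[a] <- comm_deg[a] - deg[v]
        comm_deg[b] <- comm_deg[b] + deg[v]
        mem[v] <- b
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  mem
}

.greedy_modularity <- function(g) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  # CNM greedy agglomeration polished by deterministic single-node moves;
  # a second agglomerative start (multilevel with a fixed internal seed,
  # RNG state restored afterwards) guards against poor CNM merges. The
  # whole procedure is deterministic for a given graph.
  gs <- igraph::simplify(g)
  adj <- igraph::as_adjacency_matrix(gs, sparse = FALSE)
  n <- nrow(adj)
  nb_list <- lapply(seq_len(n), function(v) which(adj[v, ] > 0))
  deg <- rowSums(adj)
  m <- sum(adj) / 2
  mem1 <- as.integer(igraph::membership(igraph::cluster_fast_greedy(gs)))
  mem2 <- .with_preserved_rng(1L, {
    as.integer(igraph::membership(igraph::cluster_louvain(gs)))
  })
  mem3 <- tryCatch(
    suppressWarnings(
      as.integer(igraph::membership(igraph::cluster_leading_eigen(gs)))),
    error = function(e) mem1)
  best <- -Inf
  for (mem in list(mem1, mem2, mem3)) {
    mem <- .refine_membership(nb_list, deg, m, mem)
    q <- igraph::modularity(gs, mem)
    if (q > best) best <- q
  }
  best
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Global topological indices of a binary network
#'
#' Computes the segregation, integration and community-structure measures of
#' the analysis: mean clustering coefficient, characteristic path length
#' (averaged over connected pairs only, with the number of connected
#' components surfaced), global efficiency, mean local efficiency,
#' transitivity, and greedy-agglomeration modularity. When a [sweep_config()]
#' is supplied, normalized clustering (gamma), normalized path length
#' (lambda) and the Small-World Index (sigma = gamma / lambda) are added,
#' using `n_random_refs` degree-preserving rewired references.
#'
#' @param bn A `binary_network`.
#' @param cfg Optional `sweep_config` enabling normalized metrics.
#' @param which Character vector of metric names to compute (subset of
#'   `clustering`, `char_path_length`, `global_efficiency`,
#'   `local_efficiency`, `modularity`, `transitivity`, `n_components`,
#'   `normalized_clustering`, `normalized_path_length`, `small_world_index`).
#'   Default: all base metrics, plus normalized ones when `cfg` is given.
#' @return A one-row tibble.
#' @export
compute_global_metrics <- function(bn, cfg = NULL, which = NULL) {
  if (nrow(bn$adjacency) < 3) {
    abort("global metrics need at least 3 nodes",
          class = "netsweep_undefined_metric_error")
  }
  if (bn$n_edges == 0) {
    abort("metrics are undefined on an empty graph",
          class = "netsweep_undefined_metric_error")
  }
  if (is.null(which)) {
    which <- c(GLOBAL_METRICS, if (!is.null(cfg)) NORMALIZED_METRICS)
  }
  g <- .as_graph(bn)
  out <- list()
  need_norm <- any(NORMALIZED_METRICS %in% which)
  need_c <- "clustering" %in% which ||
    any(c("normalized_clustering", "small_world_index") %in% which)
  need_l <- "char_path_length" %in% which ||
    any(c("normalized_path_length", "small_world_index") %in% which)
  if (need_c) out$clustering <- mean(.nodal_clustering(g))
  if (need_l) out$char_path_length <- .char_path_length(g)
  if ("global_efficiency" %in% which) {
    out$global_efficiency <- igraph::global_efficiency(g)
  }
  if ("local_efficiency" %in% which) {
    out$local_efficiency <- mean(.local_efficiency(g))
  }
  if ("transitivity" %in% which) {
    tr <- igraph::transitivity(g, type = "global")
    out$transitivity <- if (is.nan(tr)) 0 else tr
  }
  if ("modularity" %in% which) out$modularity <- .greedy_modularity(g)
  if ("n_components" %in% which || need_l) {
    out$n_components <- igraph::components(g)$no
  }
  if (need_norm) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    need_ref_l <- any(c("normalized_path_length", "small_world_index") %in%
                        which)
    ref_c <- ref_l <- numeric(cfg$n_random_refs)
    for (r in seq_len(cfg$n_random_refs)) {
      ref <- random_reference(bn, cfg, .reseed = FALSE)
      gr <- .as_graph(ref)
      ref_c[r] <- mean(.nodal_clustering(gr))
      ref_l[r] <- if (need_ref_l) .char_path_length(gr) else NA_real_
    }
    mc <- mean(ref_c)
    ml <- mean(ref_l)
    if (!is.finite(mc) || mc == 0) {
      warn("random-reference clustering is zero; normalized clustering undefined")
      gamma <- NA_real_
    } else {
      gamma <- out$clustering / mc
    }
    lambda <- if (is.finite(ml) && ml > 0) out$char_path_length / ml
              else NA_real_
    if ("normalized_clustering" %in% which) out$normalized_clustering <- gamma
    if ("normalized_path_length" %in% which) out$normalized_path_length <- lambda
    if ("small_world_index" %in% which) {
      out$small_world_index <- gamma / lambda
    }
  }
  # helper quantities computed on the way (e.g. clustering when only the
  # small-world index was requested) are returned too
  ord <- intersect(c(GLOBAL_METRICS, NORMALIZED_METRICS), names(out))
  tibble::as_tibble(out[ord])
}

#' Nodal topological indices of a binary network
#'
#' @param bn A `binary_network`.
#' @param which Nodal metric names to compute (default all); restricting the
#'   set skips the expensive ones (betweenness, local efficiency) in large
#'   sweeps.
#' @return A tibble with one row per node: `node_id` (0-based) plus the
#'   requested of `degree`, `betweenness_raw` (Brandes counts), `betweenness`
#'   (normalized by `(N-1)(N-2)/2`), `clustering`, `local_efficiency`.
#' @export
compute_nodal_metrics <- function(bn, which = NODAL_METRICS) {
  n <- nrow(bn$adjacency)
  if (n < 3) {
    abort("nodal metrics need at least 3 nodes",
          class = "netsweep_undefined_metric_error")
  }
  g <- .as_graph(bn)
  out <- list(node_id = seq_len(n) - 1L)
  if ("degree" %in% which) out$degree <- as.numeric(igraph::degree(g))
  if (any(c("betweenness", "betweenness_raw") %in% which)) {
    btw <- as.numeric(igraph::betweenness(g, directed = FALSE))
    if ("betweenness_raw" %in% which) out$betweenness_raw <- btw
    if ("betweenness" %in% which) {
      out$betweenness <- btw / ((n - 1) * (n - 2) / 2)
    }
  }
  if ("clustering" %in% which) out$clustering <- .nodal_clustering(g)
  if ("local_efficiency" %in% which) {
    out$local_efficiency <- .local_efficiency(g)
  }
  tibble::as_tibble(out)
}

#' Degree-preserving random reference network
#'
#' Maslov-Sneppen double-edge swaps: `rewire_iterations_per_edge * E`
#' attempted swaps that preserve every node's degree exactly. Connectedness is
#' not enforced.
#'
#' @param bn A `binary_network`.
#' @param cfg A [sweep_config()] (swap count and seed).
#' @param .reseed Set the RNG from `cfg$seed` (internal callers manage the
#'   RNG themselves).
#' @return A rewired `binary_network` with the same degree sequence.
#' @export
random_reference <- function(bn, cfg = sweep_config(), .reseed = TRUE) {
  if (.reseed && !is.null(cfg$seed)) set.seed(cfg$seed)
  if (bn$n_edges < 2) {
    warn("too few edges to rewire; returning a copy")
    return(bn)
  }
  g <- .as_graph(bn)
  g <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = cfg$rewire_iterations_per_edge * bn$n_edges))
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  dimnames(adj) <- NULL
  structure(list(adjacency = adj, density = bn$density,
                 n_edges = bn$n_edges, target_density = bn$target_density),
            class = "binary_network")
}

#' Metric curves across the density sweep
#'
#' Thresholds one subject's weighted connectivity matrix at every density of
#' the sweep grid and evaluates the requested global and nodal metrics,
#' returning them in long format (`node_id = "GLOBAL"` for whole-network
#' indices).
#'
#' @param m `connectivity_matrix` for one subject.
#' @param cfg A [sweep_config()].
#' @param metrics Which metrics to evaluate: any of the global metric names,
#'   the normalized names, the keyword `"nodal"` (all nodal metrics), or
#'   specific nodal names prefixed `nodal_` (e.g. `"nodal_degree"`).
#'   Default: all global + normalized + nodal.
#' @param subject_id Overrides the subject id attribute.
#' @return A `metric_curves` tibble: `subject_id`, `metric`, `node_id`,
#'   `density`, `value`.
#' @export
sweep_metrics <- function(m, cfg = sweep_config(),
                          metrics = c("global", "normalized", "nodal"),
                          subject_id = NULL) {
  subject_id <- subject_id %||% attr(m, "subject_id") %||% "subject"
  grid <- density_grid(cfg)
  req <- .expand_metric_request(metrics)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  glob <- vector("list", length(grid))
  nod <- vector("list", length(grid))
  prep <- .threshold_prep(m)
  for (k in seq_along(grid)) {
    bn <- .threshold_take(prep, grid[k])
    if (length(req$global) > 0) {
      gm <- compute_global_metrics(
        bn, cfg = if (req$need_norm) cfg else NULL, which = req$global)
      glob[[k]] <- unlist(gm[1, ])
    }
    if (length(req$nodal) > 0) {
      nod[[k]] <- as.matrix(compute_nodal_metrics(
        bn, which = req$nodal)[, req$nodal, drop = FALSE])
    }
  }
  parts <- list()
  if (length(req$global) > 0) {
    nm <- names(glob[[1]])
    parts$global <- tibble::tibble(
      metric = rep(nm, times = length(grid)),
      node_id = "GLOBAL",
      density = rep(grid, each = length(nm)),
      value = unname(unlist(glob)))
  }
  if (length(req$nodal) > 0) {
    n_nodes <- nrow(nod[[1]])
    parts$nodal <- tibble::tibble(
      metric = rep(rep(req$nodal, each = n_nodes), times = length(grid)),
      node_id = rep(as.character(seq_len(n_nodes) - 1L),
                    times = length(req$nodal) * length(grid)),
      density = rep(grid, each = n_nodes * length(req$nodal)),
      value = as.numeric(unlist(nod)))
  }
  res <- dplyr::bind_rows(parts)
  res <- tibble::tibble(subject_id = subject_id, metric = res$metric,
                        node_id = res$node_id, density = res$density,
                        value = res$value)
  class(res) <- c("metric_curves", class(res))
  attr(res, "grid") <- grid
  res
}

.expand_metric_request <- function(metrics) {
  metrics <- unique(metrics)
  glb <- character(0)
  nod <- character(0)
  for (m in metrics) {
    if (m == "global") glb <- union(glb, GLOBAL_METRICS)
    else if (m == "normalized") glb <- union(glb, NORMALIZED_METRICS)
    else if (m == "nodal") nod <- union(nod, NODAL_METRICS)
    else if (m %in% c(GLOBAL_METRICS, NORMALIZED_METRICS)) glb <- union(glb, m)
    else if (startsWith(m, "nodal_") &&
             sub("^nodal_", "", m) %in% NODAL_METRICS) {
      nod <- union(nod, sub("^nodal_", "", m))
    } else {
      abort(paste0("unknown metric: ", m), class = "netsweep_config_error")
    }
  }
  list(global = glb, nodal = nod,
       need_norm = any(NORMALIZED_METRICS %in% glb))
}

#' Sweep a whole cohort of connectivity matrices
#'
#' @param matrices List of `connectivity_matrix` objects.
#' @param cfg A [sweep_config()].
#' @inheritParams sweep_metrics
#' @return A `metric_curves` tibble covering all subjects.
#' @export
sweep_cohort <- function(matrices, cfg = sweep_config(),
                         metrics = c("global", "normalized", "nodal")) {
  res <- dplyr::bind_rows(purrr::map(matrices, sweep_metrics, cfg = cfg,
                                     metrics = metrics))
  class(res) <- c("metric_curves", class(res))
  attr(res, "grid") <- density_grid(cfg)
  res
}

#' Area under metric-versus-density curves
#'
#' Trapezoidal integral over the density grid, the threshold-free summary on
#' which all group comparisons operate.
#'
#' @param curves A `metric_curves` tibble (or any tibble with `subject_id`,
#'   `metric`, `node_id`, `density`, `value`).
#' @return A tibble: `subject_id`, `metric`, `node_id`, `auc`.
#' @export
curve_auc <- function(curves) {
  curves |>
    dplyr::group_by(.data$subject_id, .data$metric, .data$node_id) |>
    dplyr::arrange(.data$density, .by_group = TRUE) |>
    dplyr::summarise(auc = pracma::trapz(.data$density, .data$value),
                     .groups = "drop")
}
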