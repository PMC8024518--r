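# Synthetic two-group cohort generator with known ground truth.
#
# Latent model: each subject's white-matter skeleton is a Watts-Strogatz
# ring lattice (n_nodes nodes, base_degree neighbors) rewired with the
# subject's group-specific probability (plus a small subject-level jitter
# that carries individual small-worldness differences). Streamline counts
# are overdispersed nonnegative integers: negative binomial around
# edge_weight_scale x latent edge weight (Poisson when count_noise = 0),
# sampled independently in each direction, with a weak background rate on
# non-skeleton pairs emulating spurious probabilistic-tractography hits.

#' Synthetic cohort configuration
#'
#' @param n_per_group Subjects per group (patients = group a, controls =
#'   group b).
#' @param n_nodes Number of atlas nodes (default 162, the package's cortical
#'   + subcortical parcellation).
#' @param base_degree Ring-lattice neighbor count k (even, < n_nodes;
#'   default 10).
#' @param rewire_prob_group_a,rewire_prob_group_b Watts-Strogatz rewiring
#'   probability of each group's latent skeleton (default 0.1 both).
#' @param edge_weight_scale Expected streamline count on a latent edge
#'   (default 50).
#' @param count_noise Overdispersion of count sampling: negative binomial
#'   with `size = 1/count_noise`; 0 gives Poisson (default 0.5).
#' @param n_planted_hubs Number of planted hub nodes, common to both groups
#'   (default 0).
#' @param hub_boost Multiplicative weight factor (>= 1) on planted-hub edges
#'   (default 1).
#' @param bmi_swi_effect Slope linking a subject's latent small-worldness
#'   score (standardized) to simulated lowest lifetime BMI (kg/m^2 per SD;
#'   default 0).
#' @param volume_effect Slope linking a node's planted connectivity boost in
#'   the control group to its relative cortical-volume increase (default 0;
#'   when nonzero, control subjects receive per-node strength boosts
#'   `delta_j ~ U(0, 0.5)` whose magnitude is mirrored in volume means).
#' @param background_rate Latent weight of non-skeleton pairs relative to a
#'   skeleton edge (default 0.02), so thresholding above the skeleton
#'   density recruits noise edges as real tractography does.
#' @param subject_rewire_sd SD of the subject-level jitter on the rewiring
#'   probability (default 0.02).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group, n_nodes = 162, base_degree = 10,
                          rewire_prob_group_a = 0.1,
                          rewire_prob_group_b = 0.1,
                          edge_weight_scale = 50, count_noise = 0.5,
                          n_planted_hubs = 0, hub_boost = 1,
                          bmi_swi_effect = 0, volume_effect = 0,
                          background_rate = 0.02, subject_rewire_sd = 0.02,
                          seed = NULL) {
  if (length(n_per_group) != 1 || n_per_group < 1) {
    abort("n_per_group must be a positive integer",
          class = "netsweep_config_error")
  }
  if (n_nodes < 4) {
    abort("n_nodes must be at least 4", class = "netsweep_config_error")
  }
  if (base_degree %% 2 != 0 || base_degree < 2) {
    abort("base_degree must be an even positive integer",
          class = "netsweep_config_error")
  }
  if (base_degree >= n_nodes) {
    abort("base_degree must be smaller than n_nodes",
          class = "netsweep_config_error")
  }
  for (p in c(rewire_prob_group_a, rewire_prob_group_b)) {
    if (p < 0 || p > 1) {
      abort("rewire probabilities must be in [0, 1]",
            class = "netsweep_config_error")
    }
  }
  if (edge_weight_scale <= 0 || background_rate < 0 || count_noise < 0 ||
      subject_rewire_sd < 0) {
    abort("scales and dispersions must be nonnegative (edge_weight_scale > 0)",
          class = "netsweep_config_error")
  }
  if (hub_boost < 1) {
    abort("hub_boost must be >= 1", class = "netsweep_config_error")
  }
  if (n_planted_hubs < 0 || n_planted_hubs > n_nodes) {
    abort("n_planted_hubs must be in [0, n_nodes]",
          class = "netsweep_config_error")
  }
  structure(list(
    n_per_group = as.integer(n_per_group), n_nodes = as.integer(n_nodes),
    base_degree = as.integer(base_degree),
    rewire_prob_group_a = rewire_prob_group_a,
    rewire_prob_group_b = rewire_prob_group_b,
    edge_weight_scale = edge_weight_scale, count_noise = count_noise,
    n_planted_hubs = as.integer(n_planted_hubs), hub_boost = hub_boost,
    bmi_swi_effect = bmi_swi_effect, volume_effect = volume_effect,
    background_rate = background_rate, subject_rewire_sd = subject_rewire_sd,
    seed = seed), class = "cohort_config")
}

# Latent weighted adjacency for one subject: WS skeleton at rewiring p,
# hub edges boosted, control-group node boosts delta, background off-edges.
.latent_weights <- function(cfg, p_rewire, hubs, delta) {
  n <- cfg$n_nodes
  g <- igraph::sample_smallworld(1, n, cfg$base_degree / 2, p_rewire)
  w <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  dimnames(w) <- NULL
  w <- (w > 0) * 1.0
  bg <- matrix(cfg$background_rate, n, n)
  w <- ifelse(w > 0, w, bg)
  # hub boost multiplies every weight incident to a planted hub (skeleton
  # and background alike), so hubs carry both more streamline mass and more
  # supra-threshold connections across the whole density sweep
  if (length(hubs) > 0 && cfg$hub_boost > 1) {
    w[hubs, ] <- w[hubs, ] * cfg$hub_boost
    w[, hubs] <- pmax(w[, hubs], t(w[hubs, ]))
  }
  if (!is.null(delta)) {
    mult <- sqrt(outer(1 + delta, 1 + delta))
    w <- w * mult
  }
  diag(w) <- 0
  w
}

#' Generate a synthetic two-group cohort
#'
#' Produces per-subject streamline counts, a clinical table, per-node
#' volumes, the atlas, and a ground-truth record, fully reproducible from
#' `config$seed`. Group a subjects are labeled `patient`, group b `control`.
#' Seed totals default to 5000 streamlines per ROI (one nominal
#' boundary voxel at 5000 samples each).
#'
#' @param config A [cohort_config()].
#' @return A `cohort` list: `counts` (list of [streamline_counts()]),
#'   `clinical` (tibble), `volumes` (long tibble), `atlas`, `ground_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_nodes
  atlas <- if (n == 162) destrieux_atlas() else synthetic_atlas(n)
  hubs <- if (config$n_planted_hubs > 0) {
    sort(sample.int(n, config$n_planted_hubs))
  } else integer(0)
  delta <- if (config$volume_effect != 0) runif(n, 0, 0.5) else NULL

  groups <- c(a = "patient", b = "control")
  p_group <- c(a = config$rewire_prob_group_a, b = config$rewire_prob_group_b)
  seeded <- rep(5000, n)

  subj <- tidyr::expand_grid(grp = c("a", "b"),
                             idx = seq_len(config$n_per_group))
  subj$subject_id <- sprintf("%s%02d", ifelse(subj$grp == "a", "pat", "con"),
                             subj$idx)
  # subject-level jitter on the rewiring probability carries individual
  # small-worldness; score is the standardized negative deviation
  jit <- rnorm(nrow(subj), 0, config$subject_rewire_sd)
  p_subj <- pmin(pmax(p_group[subj$grp] + jit, 0), 1)
  swi_score <- if (config$subject_rewire_sd > 0) {
    -jit / config$subject_rewire_sd
  } else rep(0, nrow(subj))

  counts <- vector("list", nrow(subj))
  size <- if (config$count_noise > 0) 1 / config$count_noise else Inf
  for (i in seq_len(nrow(subj))) {
    d_i <- if (subj$grp[i] == "b") delta else NULL
    w <- .latent_weights(config, p_subj[i], hubs, d_i)
    mu <- config$edge_weight_scale * w
    cm <- matrix(0, n, n)
    off <- which(mu > 0)
    cm[off] <- if (is.finite(size)) {
      rnbinom(length(off), size = size, mu = mu[off])
    } else {
      rpois(length(off), mu[off])
    }
    cm <- pmin(cm, matrix(seeded, n, n))
    diag(cm) <- 0
    counts[[i]] <- streamline_counts(subj$subject_id[i], cm, seeded,
                                     scale = atlas$scale)
  }

  is_pat <- subj$grp == "a"
  base_bmi_low <- ifelse(is_pat, 14, 19.5)
  clinical <- tibble::tibble(
    subject_id = subj$subject_id,
    group = unname(groups[subj$grp]),
    age = round(pmax(rnorm(nrow(subj), 24, 5), 16), 1),
    handedness = round(pmin(pmax(rnorm(nrow(subj), 70, 30), -100), 100), 0),
    bmi_scan = round(ifelse(is_pat, rnorm(nrow(subj), 16.5, 1.5),
                            rnorm(nrow(subj), 21.5, 2)), 1),
    bmi_lowest = round(base_bmi_low + config$bmi_swi_effect * swi_score +
                         rnorm(nrow(subj), 0, 1), 1),
    swi_score = swi_score)

  base_vol <- runif(n, 2000, 12000)
  vol_rows <- purrr::map(seq_len(nrow(subj)), function(i) {
    mult <- if (subj$grp[i] == "b" && !is.null(delta)) {
      1 + config$volume_effect * delta
    } else rep(1, n)
    tibble::tibble(subject_id = subj$subject_id[i],
                   group = unname(groups[subj$grp[i]]),
                   node_id = seq_len(n) - 1L,
                   volume = base_vol * mult * exp(rnorm(n, 0, 0.05)))
  })
  volumes <- dplyr::bind_rows(vol_rows)

  ground_truth <- list(
    hub_nodes = hubs - 1L, # 0-based, matching atlas node ids
    group_rewire = c(patient = config$rewire_prob_group_a,
                     control = config$rewire_prob_group_b),
    base_degree = config$base_degree,
    swi_score = setNames(swi_score, subj$subject_id),
    bmi_swi_effect = config$bmi_swi_effect,
    volume_effect = config$volume_effect,
    node_boost = if (is.null(delta)) rep(0, n) else delta,
    group_effect = config$rewire_prob_group_a != config$rewire_prob_group_b ||
      config$volume_effect != 0)

  structure(list(counts = counts, clinical = clinical, volumes = volumes,
                 atlas = atlas, ground_truth = ground_truth,
                 config = config),
            class = "cohort")
}

#' Generate a null cohort (no group differences)
#'
#' Convenience wrapper around [generate_cohort()] with both groups forced to
#' the group-a generative parameters and all effect slopes set to zero.
#'
#' @param config A [cohort_config()].
#' @return A `cohort`; its `ground_truth$group_effect` is `FALSE`.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  null_cfg <- config
  null_cfg$rewire_prob_group_b <- null_cfg$rewire_prob_group_a
  null_cfg$bmi_swi_effect <- 0
  null_cfg$volume_effect <- 0
  generate_cohort(null_cfg)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects (%d per group), %d nodes, %d planted hubs\n",
    length(x$counts), x$config$n_per_group, x$config$n_nodes,
    x$config$n_planted_hubs))
  invisible(x)
}

#' Write a cohort to disk in the package's exchange formats
#'
#' One counts TSV per subject, `clinical.csv`, `volumes.tsv`, `nodes.tsv`,
#' and a `ground_truth.json` sidecar.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  for (sc in cohort$counts) {
    save_counts(sc, file.path(dir, "counts", paste0(sc$subject_id, ".tsv")))
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_tsv(cohort$volumes, file.path(dir, "volumes.tsv"))
  save_node_table(cohort$atlas, file.path(dir, "nodes.tsv"))
  gt <- cohort$ground_truth
  gt$swi_score <- as.list(gt$swi_score)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
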