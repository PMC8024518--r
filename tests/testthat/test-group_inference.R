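# helper: long curves tibble from a subjects x grid matrix of values
curves_from_matrix <- function(vals, group, grid = seq(0.02, 0.2, 0.02),
                               node_id = "GLOBAL") {
  n <- nrow(vals)
  tidyr::expand_grid(subject = seq_len(n), gi = seq_along(grid)) |>
    dplyr::mutate(subject_id = sprintf("s%02d", subject),
                  group = group[subject], density = grid[gi],
                  value = vals[cbind(subject, gi)], metric = "test_metric",
                  node_id = node_id) |>
    dplyr::select(subject_id, group, metric, node_id, density, value)
}

test_that("identical groups give zero statistic and p = 1", {
  set.seed(1)
  vals <- matrix(rnorm(4 * 10), 4, 10)
  vals <- rbind(vals, vals) # group b is the same multiset as group a
  cur <- curves_from_matrix(vals, rep(c("a", "b"), each = 4))
  res <- fda_auc_test(cur, perm_config(n_permutations = 200, seed = 3))
  expect_equal(res$observed_stat, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
})

test_that("swapping group labels negates the statistic and keeps p", {
  set.seed(2)
  vals <- matrix(rnorm(12 * 10, mean = rep(c(1, 0), each = 6)), 12, 10)
  grp <- rep(c("a", "b"), each = 6)
  cur <- curves_from_matrix(vals, grp)
  r1 <- fda_auc_test(cur, perm_config(n_permutations = 300, seed = 5),
                     groups = c("a", "b"))
  r2 <- fda_auc_test(cur, perm_config(n_permutations = 300, seed = 5),
                     groups = c("b", "a"))
  expect_equal(r1$observed_stat, -r2$observed_stat, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("permutation p-values are invariant to subject ordering", {
  set.seed(3)
  vals <- matrix(rnorm(10 * 10), 10, 10)
  grp <- rep(c("a", "b"), each = 5)
  cur <- curves_from_matrix(vals, grp)
  shuffled <- dplyr::slice_sample(cur, prop = 1)
  r1 <- fda_auc_test(cur, perm_config(n_permutations = 200, seed = 11),
                     groups = c("a", "b"))
  r2 <- fda_auc_test(shuffled, perm_config(n_permutations = 200, seed = 11),
                     groups = c("a", "b"))
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$observed_stat, r2$observed_stat)
})

test_that("grid mismatches and undersized groups are rejected", {
  set.seed(4)
  vals <- matrix(rnorm(4 * 10), 4, 10)
  cur <- curves_from_matrix(vals, rep(c("a", "b"), each = 2))
  bad <- dplyr::mutate(cur, density = ifelse(subject_id == "s01" &
                                               density == 0.02, 0.03, density))
  expect_error(fda_auc_test(bad, perm_config(n_permutations = 100)),
               class = "netsweep_grid_mismatch_error")
  solo <- dplyr::filter(cur, subject_id != "s01")
  expect_error(fda_auc_test(solo, perm_config(n_permutations = 100)),
               class = "netsweep_insufficient_group_error")
})

test_that("doubling the permutation count moves p by less than 2/sqrt(B)", {
  set.seed(6)
  bound <- 2 / sqrt(200)
  diffs <- replicate(50, {
    vals <- matrix(rnorm(12 * 5, mean = rep(c(0.4, 0), each = 6)), 12, 5)
    cur <- curves_from_matrix(vals, rep(c("a", "b"), each = 6),
                              grid = seq(0.02, 0.1, 0.02))
    p1 <- fda_auc_test(cur, perm_config(n_permutations = 200, seed = 21),
                       groups = c("a", "b"))$p_value
    p2 <- fda_auc_test(cur, perm_config(n_permutations = 400, seed = 22),
                       groups = c("a", "b"))$p_value
    abs(p1 - p2)
  })
  expect_gte(mean(diffs < bound), 0.9)
})

test_that("Benjamini-Hochberg adjustment matches its closed forms", {
  # constant raw p: adjustment is the identity
  expect_equal(p.adjust(rep(0.01, 10), method = "BH"), rep(0.01, 10))
  # textbook step-up case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
})

test_that("regional tests adjust per-node p-values and keep ensembles", {
  set.seed(7)
  n_sub <- 12
  n_nodes <- 6
  grid <- seq(0.02, 0.1, 0.02)
  grp <- rep(c("a", "b"), each = n_sub / 2)
  rows <- list()
  shift <- c(2, rep(0, n_nodes - 1)) # only node 0 differs
  for (s in seq_len(n_sub)) {
    for (v in seq_len(n_nodes)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sprintf("s%02d", s), group = grp[s],
        node_id = as.character(v - 1), density = grid,
        value = rnorm(length(grid), ifelse(grp[s] == "a", shift[v], 0), 0.3))
    }
  }
  cur <- dplyr::bind_rows(rows)
  rt <- regional_tests(cur, perm_config(n_permutations = 300, seed = 8),
                       groups = c("a", "b"), metric = "degree")
  expect_equal(nrow(rt), n_nodes)
  expect_true(all(rt$p_fdr >= rt$p_value - 1e-12))
  expect_true(rt$significant[rt$node_id == "0"])
  expect_equal(dim(attr(rt, "perm_mean_a")), c(300, n_nodes))
})

test_that("a regular group yields no hubs under the within-network rule", {
  # every node identical: no node can exceed mean + 2 SD of a constant
  set.seed(9)
  grid <- seq(0.02, 0.1, 0.02)
  rows <- tidyr::expand_grid(s = 1:8, v = 1:10, density = grid) |>
    dplyr::mutate(subject_id = sprintf("s%02d", s),
                  group = rep(c("a", "b"), each = 4)[s],
                  node_id = as.character(v - 1), value = 4)
  rt <- regional_tests(rows, perm_config(n_permutations = 100, seed = 2),
                       groups = c("a", "b"), metric = "degree")
  expect_warning(
    hubs <- identify_hubs(rt, group = "a", rule = "within_network_2sd"),
    "zero variance")
  expect_false(any(hubs$is_hub))
  # the per-node permutation rule degenerates the same way, with a warning
  expect_warning(ph <- identify_hubs(rt, group = "a",
                                     rule = "permutation_2sd"),
                 "zero-variance")
  expect_false(any(ph$is_hub))
})

test_that("a star-graph group has exactly the center as betweenness hub", {
  m <- matrix(0, 8, 8)
  m[1, 2:8] <- m[2:8, 1] <- 1
  bn <- threshold_to_density(connectivity_matrix(m), 7 / 28)
  nm <- compute_nodal_metrics(bn)
  grid <- seq(0.02, 0.1, 0.02)
  rows <- tidyr::expand_grid(s = 1:8, v = 1:8, density = grid) |>
    dplyr::mutate(subject_id = sprintf("s%02d", s),
                  group = rep(c("a", "b"), each = 4)[s],
                  node_id = as.character(v - 1),
                  value = nm$betweenness[v])
  rt <- regional_tests(rows, perm_config(n_permutations = 100, seed = 2),
                       groups = c("a", "b"), metric = "betweenness")
  hubs <- identify_hubs(rt, group = "a", rule = "within_network_2sd")
  expect_identical(hubs$node_id[hubs$is_hub], "0")
})

test_that("group-level comparison mode runs and is seeded", {
  set.seed(10)
  mats <- purrr::map(1:6, function(i) {
    w <- matrix(runif(20^2), 20, 20)
    connectivity_matrix((w + t(w)) / 2, subject_id = paste0("s", i))
  })
  grp <- rep(c("a", "b"), each = 3)
  cfg <- suppressWarnings(perm_config(n_permutations = 20, seed = 5))
  scfg <- sweep_config(d_min = 0.05, d_max = 0.15, d_step = 0.05,
                       n_random_refs = 2, seed = 1)
  suppressWarnings({
    r1 <- group_auc_test(mats, grp, metric = "clustering", scfg, cfg)
    r2 <- group_auc_test(mats, grp, metric = "clustering", scfg, cfg)
  })
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$observed_stat, r2$observed_stat)
  expect_length(r1$null_distribution, 20)
})

test_that("tidy and glance summarise permutation tests", {
  set.seed(12)
  vals <- matrix(rnorm(8 * 10), 8, 10)
  cur <- curves_from_matrix(vals, rep(c("a", "b"), each = 4))
  res <- fda_auc_test(cur, perm_config(n_permutations = 100, seed = 1),
                      groups = c("a", "b"))
  td <- tidy(res)
  expect_equal(td$observed_stat, res$observed_stat)
  gl <- glance(res)
  expect_equal(gl$n_permutations, 100L)
  expect_equal(gl$n_a, 4L)
})
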