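make_bn <- function(adj) {
  n <- nrow(adj)
  structure(list(adjacency = adj, density = sum(adj) / (n * (n - 1)),
                 n_edges = sum(adj) / 2, target_density = NA_real_),
            class = "binary_network")
}

test_that("thresholding retains the forced edge counts at the grid endpoints", {
  set.seed(1)
  w <- matrix(runif(162^2, 0.01, 1), 162, 162)
  m <- connectivity_matrix((w + t(w)) / 2)
  expect_equal(threshold_to_density(m, 0.02)$n_edges, 261)  # round(.02*13041)
  expect_equal(threshold_to_density(m, 0.2)$n_edges, 2608)  # round(.2*13041)
})

test_that("ties at the cutoff break by ascending (i, j) and are reproducible", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5
  w[1, 3] <- w[3, 1] <- 3
  w[2, 4] <- w[4, 2] <- 3 # ties with (1,3); (1,3) is the smaller pair
  bn1 <- threshold_to_density(connectivity_matrix(w), 2 / 6)
  bn2 <- threshold_to_density(connectivity_matrix(w), 2 / 6)
  expect_equal(bn1$n_edges, 2)
  expect_equal(bn1$adjacency[1, 3], 1)
  expect_equal(bn1$adjacency[2, 4], 0)
  expect_identical(bn1$adjacency, bn2$adjacency)
})

test_that("edge sets are nested across the density sweep", {
  set.seed(2)
  w <- matrix(runif(40^2), 40, 40)
  m <- connectivity_matrix((w + t(w)) / 2)
  grid <- density_grid(sweep_config())
  prev <- NULL
  for (d in grid) {
    adj <- threshold_to_density(m, d)$adjacency
    if (!is.null(prev)) expect_true(all(adj[prev == 1] == 1))
    prev <- adj
  }
})

test_that("thresholding flags empty and shortfall cases", {
  m <- connectivity_matrix(matrix(0, 6, 6))
  expect_error(threshold_to_density(m, 0.01),
               class = "netsweep_empty_network_error")
  w <- matrix(0, 10, 10)
  w[1, 2] <- w[2, 1] <- 1
  expect_warning(bn <- threshold_to_density(connectivity_matrix(w), 0.5),
                 "shortfall")
  expect_equal(bn$n_edges, 1)
})

test_that("triangle and star metrics take their closed-form values", {
  k3 <- make_bn(matrix(1, 3, 3) - diag(3))
  gm <- compute_global_metrics(k3)
  expect_equal(gm$clustering, 1)
  expect_equal(gm$char_path_length, 1)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$transitivity, 1)

  star <- matrix(0L, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1L
  gs <- compute_global_metrics(make_bn(star))
  expect_equal(gs$clustering, 0)
  expect_equal(gs$transitivity, 0)
  expect_equal(gs$char_path_length, 1.5)
  ns <- compute_nodal_metrics(make_bn(star))
  expect_equal(ns$betweenness_raw[1], 3)
  expect_equal(ns$betweenness_raw[2:4], rep(0, 3))
})

test_that("path and cycle betweenness follow symmetry", {
  p3 <- matrix(0L, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1L
  nb <- compute_nodal_metrics(make_bn(p3))
  expect_equal(nb$betweenness_raw, c(0, 1, 0))

  c5 <- matrix(0L, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    c5[i, j] <- c5[j, i] <- 1L
  }
  nb5 <- compute_nodal_metrics(make_bn(c5))
  expect_true(all(nb5$betweenness_raw == nb5$betweenness_raw[1]))
})

test_that("random 6-node graphs agree with the brute-force oracle", {
  set.seed(31)
  for (rep in 1:25) {
    adj <- random_adjacency(6, runif(1, 0.25, 0.85))
    if (sum(adj) == 0) next
    o <- oracle_metrics(adj)
    gm <- compute_global_metrics(make_bn(adj))
    nm <- compute_nodal_metrics(make_bn(adj))
    expect_equal(gm$clustering, o$clustering_mean, tolerance = 1e-12)
    expect_equal(gm$transitivity, o$transitivity, tolerance = 1e-12)
    expect_equal(gm$char_path_length, o$char_path_length, tolerance = 1e-12)
    expect_equal(gm$global_efficiency, o$global_efficiency, tolerance = 1e-12)
    expect_equal(gm$local_efficiency, mean(o$local_efficiency),
                 tolerance = 1e-12)
    expect_equal(nm$degree, o$degree, tolerance = 1e-12)
    expect_equal(nm$betweenness_raw, o$betweenness, tolerance = 1e-12)
    expect_equal(nm$clustering, o$clustering, tolerance = 1e-12)
    expect_equal(nm$local_efficiency, o$local_efficiency, tolerance = 1e-12)
  }
})

test_that("ring lattice clustering equals 3(k-2)/(4(k-1)) exactly", {
  for (k in c(4, 6, 10)) {
    g <- igraph::sample_smallworld(1, 60, k / 2, 0)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    dimnames(adj) <- NULL
    gm <- compute_global_metrics(make_bn(adj), which = "clustering")
    expect_equal(gm$clustering, 3 * (k - 2) / (4 * (k - 1)), tolerance = 1e-12)
  }
})

test_that("random references preserve the degree sequence exactly", {
  set.seed(4)
  w <- matrix(runif(50^2), 50, 50)
  bn <- threshold_to_density(connectivity_matrix((w + t(w)) / 2), 0.1)
  cfg <- sweep_config(seed = 99)
  ref <- random_reference(bn, cfg)
  expect_equal(rowSums(ref$adjacency), rowSums(bn$adjacency))
  expect_false(identical(ref$adjacency, bn$adjacency))
})

test_that("rewired references destroy lattice clustering", {
  set.seed(5)
  g <- igraph::sample_smallworld(1, 162, 2, 0)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(adj) <- NULL
  bn <- make_bn(adj)
  cfg <- sweep_config(n_random_refs = 20, seed = 7)
  c_in <- compute_global_metrics(bn, which = "clustering")$clustering
  c_refs <- replicate(20, {
    ref <- random_reference(bn, cfg, .reseed = FALSE)
    compute_global_metrics(ref, which = "clustering")$clustering
  })
  expect_lt(mean(c_refs), 0.5 * c_in)
})

test_that("degree curves are non-decreasing in density and AUC is trapezoidal", {
  set.seed(6)
  w <- matrix(runif(30^2), 30, 30)
  m <- connectivity_matrix((w + t(w)) / 2, subject_id = "s1")
  cfg <- sweep_config(n_random_refs = 2, seed = 1)
  cur <- sweep_metrics(m, cfg, metrics = "nodal_degree")
  by_node <- dplyr::group_by(cur, node_id)
  deltas <- dplyr::summarise(
    dplyr::arrange(by_node, density, .by_group = TRUE),
    ok = all(diff(value) >= 0), .groups = "drop")
  expect_true(all(deltas$ok))

  const <- tibble::tibble(subject_id = "s", metric = "m", node_id = "GLOBAL",
                          density = density_grid(cfg), value = 3.5)
  expect_equal(curve_auc(const)$auc, 0.18 * 3.5, tolerance = 1e-12)
})

test_that("the default density grid spans 0.02-0.2 inclusive in 10 steps", {
  grid <- density_grid(sweep_config())
  expect_length(grid, 10)
  expect_equal(grid[1], 0.02)
  expect_equal(grid[10], 0.2)
  expect_equal(diff(grid), rep(0.02, 9), tolerance = 1e-9)
})

test_that("sweep configs reject degenerate grids", {
  expect_error(sweep_config(d_min = 0), class = "netsweep_config_error")
  expect_error(sweep_config(d_min = 0.5, d_max = 0.2),
               class = "netsweep_config_error")
  expect_error(sweep_config(d_min = 0.1, d_max = 0.1, d_step = 0.2),
               class = "netsweep_config_error")
})
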