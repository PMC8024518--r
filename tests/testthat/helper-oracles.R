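# Independent brute-force oracles for graph metrics: explicit triangle and
# simple-path enumeration, exhaustive modularity over all partitions.
# Deliberately naive and separate from the package implementation.

# all simple paths between s and t by depth-first enumeration;
# returns a list of integer vectors (node sequences incl. endpoints)
oracle_all_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(path, visited) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] == 1)) {
      if (!visited[w]) {
        visited[w] <- TRUE
        walk(c(path, w), visited)
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  walk(s, visited)
  paths
}

# all-pairs shortest-path lengths, shortest-path counts, and per-node
# pass-through counts, from explicit path enumeration
oracle_paths_summary <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_all_paths(adj, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1)) - 1L
      d <- min(lens)
      dist[s, t] <- dist[t, s] <- d
      shortest <- paths[lens == d]
      sigma <- length(shortest)
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        btw[interior] <- btw[interior] + 1 / sigma
      }
    }
  }
  list(dist = dist, betweenness = btw)
}

oracle_degree <- function(adj) rowSums(adj)

# per-node clustering by explicit neighbour-pair counting; degree<2 -> 0
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

# transitivity = 3 * triangles / connected triples, by triple enumeration
oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  tri <- 0
  triples <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k >= 2) triples <- triples + k * (k - 1) / 2
    if (k >= 2) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
  }
  if (triples == 0) return(0)
  # each triangle is counted once per corner = 3 times
  tri / triples
}

oracle_global_from_dist <- function(dist) {
  n <- nrow(dist)
  d <- dist[upper.tri(dist)]
  fin <- d[is.finite(d)]
  list(
    char_path_length = if (length(fin) > 0) mean(fin) else NA_real_,
    global_efficiency = mean(ifelse(is.finite(d), 1 / d, 0))
  )
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ps <- oracle_paths_summary(sub)
    oracle_global_from_dist(ps$dist)$global_efficiency
  }, numeric(1))
}

oracle_metrics <- function(adj) {
  ps <- oracle_paths_summary(adj)
  g <- oracle_global_from_dist(ps$dist)
  cl <- oracle_clustering(adj)
  list(
    degree = oracle_degree(adj),
    betweenness = ps$betweenness,
    clustering = cl,
    clustering_mean = mean(cl),
    transitivity = oracle_transitivity(adj),
    char_path_length = g$char_path_length,
    global_efficiency = g$global_efficiency,
    local_efficiency = oracle_local_efficiency(adj)
  )
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
oracle_partitions <- function(n) {
  out <- list()
  grow <- function(m) {
    if (length(m) == n) {
      out[[length(out) + 1]] <<- m
      return(invisible())
    }
    for (b in seq_len(max(m) + 1)) grow(c(m, b))
  }
  grow(1L)
  out
}

# maximum modularity over every partition (Newman-Girvan Q)
oracle_max_modularity <- function(adj) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  deg <- rowSums(adj)
  best <- -Inf
  for (part in oracle_partitions(nrow(adj))) {
    q <- 0
    for (b in unique(part)) {
      idx <- which(part == b)
      e_in <- sum(adj[idx, idx]) / 2
      d_in <- sum(deg[idx])
      q <- q + e_in / m - (d_in / (2 * m))^2
    }
    best <- max(best, q)
  }
  best
}

# Mann-Whitney U by exhaustive pair enumeration (ties count 1/2)
oracle_u_stat <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

# adjacency matrix for graph index 'code' on n nodes (bits of the upper
# triangle, row-major)
graph_from_code <- function(code, n) {
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  bits <- as.integer(intToBits(code))[seq_along(ut)]
  adj[ut[bits == 1]] <- 1L
  adj + t(adj)
}

random_adjacency <- function(n, p = 0.5) {
  adj <- matrix(0L, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- as.integer(runif(sum(ut)) < p)
  adj + t(adj)
}
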