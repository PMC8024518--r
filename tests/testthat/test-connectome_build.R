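test_that("probability matrix follows the scaled conditional-probability formula", {
  counts <- matrix(0L, 3, 3)
  counts[2, 3] <- 50L
  counts[3, 2] <- 30L
  sc <- streamline_counts("s1", counts, seeded = rep(5000, 3))
  p <- compute_probability_matrix(sc)
  expect_equal(p[2, 3], (50 / 5000 + 30 / 5000) / 2) # = 0.008
  expect_equal(p[3, 2], 0.008)
  expect_equal(p[1, 2], 0)
})

test_that("all-zero counts give the zero matrix", {
  sc <- streamline_counts("s", matrix(0L, 4, 4), seeded = rep(10, 4))
  expect_true(all(compute_probability_matrix(sc) == 0))
})

test_that("degenerate seeds and inconsistent counts are rejected by name", {
  counts <- matrix(0L, 3, 3)
  expect_error(streamline_counts("s", counts, seeded = c(10, 0, 10)),
               class = "netsweep_degenerate_seed_error")
  expect_error(streamline_counts("s", counts, seeded = c(10, 0, 10)),
               regexp = "ROI 1")
  counts[1, 2] <- 20L
  expect_error(streamline_counts("s", counts, seeded = rep(10, 3)),
               class = "netsweep_inconsistent_counts_error")
})

test_that("probability matrices are exactly symmetric, zero-diagonal, in range", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    seeded <- sample(100:500, n, replace = TRUE)
    counts <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      counts[i, -i] <- sample(0:seeded[i], n - 1, replace = TRUE)
    }
    scale <- runif(n, 0.5, 2)
    p <- compute_probability_matrix(streamline_counts("s", counts, seeded,
                                                      scale))
    expect_identical(unclass(p), t(unclass(p)))
    expect_true(all(diag(p) == 0))
    expect_true(all(p >= 0 & p <= max(scale)))
  }
})

test_that("scaling counts and seeds together leaves the matrix unchanged", {
  set.seed(3)
  n <- 6
  seeded <- rep(200, n)
  counts <- matrix(sample(0:100, n * n, replace = TRUE), n, n)
  diag(counts) <- 0L
  p1 <- compute_probability_matrix(streamline_counts("s", counts, seeded))
  k <- 7L
  counts2 <- counts
  counts2[3, ] <- counts[3, ] * k
  seeded2 <- seeded
  seeded2[3] <- seeded[3] * k
  p2 <- compute_probability_matrix(streamline_counts("s", counts2, seeded2))
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-14)
})

test_that("residualization honours its mean-preservation contracts", {
  set.seed(5)
  x <- matrix(rnorm(30 * 8, mean = 4), 30, 8)
  cov_const <- data.frame(age = rep(25, 30), handedness = rep(80, 30))
  expect_warning(out <- residualize(x, cov_const), "collinear")
  expect_equal(out, x, tolerance = 1e-9)

  cov <- data.frame(age = runif(30, 18, 40), handedness = runif(30, -90, 90))
  xlin <- matrix(2 + 3 * cov$age, ncol = 1)
  out <- residualize(xlin, cov)
  expect_equal(as.numeric(out), rep(mean(xlin), 30), tolerance = 1e-9)

  out <- residualize(x, cov)
  expect_equal(colMeans(out), colMeans(x), tolerance = 1e-9)
})

test_that("residualization is idempotent", {
  set.seed(6)
  x <- matrix(rnorm(25 * 5, 10), 25, 5)
  cov <- data.frame(age = rnorm(25, 30, 6), handedness = rnorm(25, 40, 30))
  once <- residualize(x, cov)
  twice <- residualize(once, cov)
  expect_equal(once, twice, tolerance = 1e-9)
})

test_that("residualize rejects undersized or incomplete inputs", {
  cov <- data.frame(age = c(20, 30), handedness = c(10, 20))
  expect_error(residualize(matrix(1:4, 2, 2), cov),
               class = "netsweep_insufficient_data_error")
  cov3 <- data.frame(age = c(20, 30, 40))
  expect_error(residualize(matrix(rnorm(9), 3, 3), cov3),
               class = "netsweep_schema_error")
})

test_that("matrix TSV round-trip is exact to 1e-12", {
  set.seed(9)
  atlas <- destrieux_atlas()
  w <- matrix(runif(162^2), 162, 162)
  m <- connectivity_matrix((w + t(w)) / 2, subject_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  save_matrix(m, path)
  m2 <- load_matrix(path, atlas, subject_id = "rt")
  expect_lt(max(abs(unclass(m) - unclass(m2))), 1e-12)
})

test_that("streamline-count files round-trip and schema errors are caught", {
  set.seed(10)
  atlas <- synthetic_atlas(8)
  counts <- matrix(sample(0:50, 64, replace = TRUE), 8, 8)
  diag(counts) <- 0L
  sc <- streamline_counts("sub1", counts, seeded = rep(100, 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  save_counts(sc, path)
  sc2 <- load_counts(path, atlas, subject_id = "sub1")
  expect_equal(sc2$counts, sc$counts, ignore_attr = TRUE)
  expect_equal(sc2$seeded, sc$seeded)

  expect_error(load_counts(path, synthetic_atlas(9)),
               class = "netsweep_schema_error")
})

test_that("GraphML export of a triangle has 3 nodes and 3 edges", {
  m <- connectivity_matrix(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(m, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
})

test_that("clinical and volume loaders validate their schemas", {
  clin <- tibble::tibble(subject_id = c("a", "b"),
                         group = c("patient", "control"),
                         age = c(20, 25), handedness = c(80, -10),
                         bmi_scan = c(16, 21), bmi_lowest = c(13, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(clin, path)
  expect_equal(nrow(load_clinical(path)), 2)

  bad <- clin
  bad$group <- c("case", "control")
  readr::write_csv(bad, path)
  expect_error(load_clinical(path), class = "netsweep_schema_error")

  atlas <- synthetic_atlas(4)
  vols <- tidyr::expand_grid(subject_id = c("a", "b"), node_id = 0:3)
  vols$volume <- runif(8, 1000, 2000)
  vpath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(vols, vpath)
  expect_equal(nrow(load_volumes(vpath, atlas)), 8)
  vols$node_id[1] <- 9L
  readr::write_tsv(vols, vpath)
  expect_error(load_volumes(vpath, atlas), class = "netsweep_schema_error")
})

test_that("default atlas matches the 148 + 14 parcellation", {
  atlas <- destrieux_atlas()
  expect_equal(nrow(atlas), 162)
  expect_equal(sum(atlas$is_cortical), 148)
  expect_equal(sum(!atlas$is_cortical), 14)
  expect_equal(atlas$node_id, 0:161)
  expect_false(anyDuplicated(atlas$name) > 0)
  expect_setequal(unique(atlas$hemisphere), c("left", "right"))
})
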