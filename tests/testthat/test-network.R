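test_that("global edge threshold is the pooled median", {
  expect_equal(global_edge_threshold(c(1, 2, 3, 4, 5)), 3)
  expect_equal(global_edge_threshold(c(1, 2, 3, 4)), 2.5)
  set.seed(12)
  v <- runif(200)
  s <- sort(v)
  expect_equal(global_edge_threshold(v), (s[100] + s[101]) / 2)
  expect_error(global_edge_threshold(numeric(0)), "no edge values")
})

test_that("networks retain edges at or above threshold and exclude Pb", {
  vals <- seq(0.1, 0.3, length.out = 21)
  edges <- full_edge_table(vals)
  net_all <- build_network(edges, "rr", threshold = 0)
  expect_equal(sum(net_all$weights[upper.tri(net_all$weights)] > 0), 21)
  expect_false("Pb" %in% rownames(net_all$weights))
  expect_identical(net_all$weights, t(net_all$weights))
  expect_true(all(diag(net_all$weights) == 0))

  net_none <- build_network(edges, "rr", threshold = 1)
  expect_true(all(net_none$weights == 0))
  nm <- node_metrics(net_none)
  expect_true(all(nm[graph_metrics()] == 0))

  # ties at the median are retained: 21 values, median = 11th smallest
  thr <- median(vals)
  net_med <- build_network(edges, "rr", threshold = thr)
  expect_equal(sum(net_med$weights[upper.tri(net_med$weights)] > 0), 11)

  expect_error(build_network(edges[-3, ], "rr", 0), "missing element pair")
})

test_that("shortest paths use reciprocal weights and flag unreachable nodes", {
  w <- matrix(0, 7, 7)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  net <- net_from_matrix(w)
  d <- shortest_path_distances(net)
  expect_equal(d[1, 3], 2)
  expect_true(all(is.infinite(d[1, 4:7])))
  # indirect route beats a weak direct edge
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 2
  w2[2, 3] <- w2[3, 2] <- 2
  w2[1, 3] <- w2[3, 1] <- 0.1
  net2 <- net_from_matrix(w2)
  expect_equal(shortest_path_distances(net2)[1, 3], 1)
})

test_that("strength sums incident weights (handshake identity)", {
  w <- matrix(0, 7, 7)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- 0.2
  net <- net_from_matrix(w)
  expect_equal(unname(degree_strength(net)[1:3]), rep(0.4, 3))
  expect_equal(unname(degree_strength(net)[4]), 0)
  set.seed(13)
  wr <- rand_weight_matrix(7)
  netr <- net_from_matrix(wr)
  expect_equal(sum(degree_strength(netr)),
               2 * sum(wr[upper.tri(wr)]))
})

test_that("hand-computed closeness, eccentricity, betweenness on small graphs", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  net <- net_from_matrix(w)
  pm <- path_metrics(net)
  expect_equal(unname(pm$closeness), c(2 / 3, 1, 2 / 3))
  expect_equal(unname(pm$eccentricity), c(2, 1, 2))
  expect_equal(unname(betweenness_centrality(net)), c(0, 1, 0))
  # complete graph, equal weights
  wc <- matrix(0.5, 4, 4); diag(wc) <- 0
  netc <- net_from_matrix(wc)
  pmc <- path_metrics(netc)
  expect_equal(unname(pmc$eccentricity), rep(2, 4))   # 1/w
  expect_equal(unname(betweenness_centrality(netc)), rep(0, 4))
})

test_that("eigenvector centrality has closed-form values and scale invariance", {
  wt <- matrix(0.3, 3, 3); diag(wt) <- 0
  expect_equal(unname(eigenvector_centrality(net_from_matrix(wt))),
               rep(1 / sqrt(3), 3), tolerance = 1e-12)
  wp <- matrix(0, 3, 3)
  wp[1, 2] <- wp[2, 1] <- 0.4
  wp[2, 3] <- wp[3, 2] <- 0.4
  v <- eigenvector_centrality(net_from_matrix(wp))
  expect_equal(unname(v), c(0.5, sqrt(2) / 2, 0.5), tolerance = 1e-12)
  v2 <- eigenvector_centrality(net_from_matrix(wp * 7.3))
  expect_equal(v, v2, tolerance = 1e-12)
  expect_equal(unname(eigenvector_centrality(net_from_matrix(matrix(0, 3, 3)))),
               rep(0, 3))
})

test_that("clustering coefficient: triangle saturates, path has none", {
  wt <- matrix(0.3, 3, 3); diag(wt) <- 0
  expect_equal(unname(clustering_coefficient(net_from_matrix(wt))),
               rep(1, 3))
  wp <- matrix(0, 3, 3)
  wp[1, 2] <- wp[2, 1] <- 0.4
  wp[2, 3] <- wp[3, 2] <- 0.4
  expect_equal(unname(clustering_coefficient(net_from_matrix(wp))),
               rep(0, 3))
})

test_that("all six metrics match brute-force oracles on random small graphs", {
  set.seed(71)
  for (r in 1:40) {
    n <- sample(3:5, 1)
    w <- rand_weight_matrix(n, p_edge = runif(1, 0.3, 0.9))
    net <- net_from_matrix(w)
    expect_equal(unname(degree_strength(net)), rowSums(w), tolerance = 1e-9)
    oc <- oracle_closeness_ecc(w)
    pm <- path_metrics(net)
    expect_equal(unname(pm$closeness), oc$closeness, tolerance = 1e-9)
    expect_equal(unname(pm$eccentricity), oc$eccentricity, tolerance = 1e-9)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(w),
                 tolerance = 1e-9)
    expect_equal(unname(eigenvector_centrality(net)), oracle_eigenvector(w),
                 tolerance = 1e-7)
    expect_equal(unname(clustering_coefficient(net)), oracle_clustering(w),
                 tolerance = 1e-9)
  }
})

test_that("metrics are equivariant under node relabelling", {
  set.seed(72)
  w <- rand_weight_matrix(7)
  net <- net_from_matrix(w)
  base <- node_metrics(net)
  perm <- sample(7)
  wp <- w[perm, perm]
  netp <- net_from_matrix(wp)
  permuted <- node_metrics(netp)
  # identify rows by original index through the permutation
  for (met in graph_metrics()) {
    expect_equal(permuted[[met]], base[[met]][perm], tolerance = 1e-9)
  }
})

test_that("adding edges and raising thresholds behave monotonically", {
  set.seed(73)
  vals <- runif(21, 0.1, 1)
  edges <- full_edge_table(vals)
  thresholds <- sort(runif(10, 0, 1.1))
  counts <- vapply(thresholds, function(th) {
    net <- build_network(edges, "rr", th)
    sum(net$weights[upper.tri(net$weights)] > 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  net0 <- build_network(edges, "rr", 0.5)
  s0 <- degree_strength(net0)
  edges2 <- edges
  drop_idx <- which(edges2$rr < 0.5)[1]
  edges2$rr[drop_idx] <- 0.9          # adds one retained edge
  net1 <- build_network(edges2, "rr", 0.5)
  expect_true(all(degree_strength(net1) >= s0 - 1e-12))
})

test_that("graphml export writes one file per subject", {
  set.seed(74)
  nets <- list(S001 = net_from_matrix(rand_weight_matrix(7)),
               S002 = net_from_matrix(rand_weight_matrix(7)))
  dir <- withr::local_tempdir()
  export_graphml(nets, dir)
  files <- list.files(dir)
  expect_length(files, 2)
  expect_true(all(grepl("\\.graphml$", files)))
})
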