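test_that("edge density handles plain and cross-partition scopes", {
  expect_equal(edge_density(complete_graph(3)), 1.0)
  expect_equal(edge_density(matrix(0L, 10, 10)), 0.0)
  set.seed(2)
  a <- random_graph(300, 5200)
  expect_equal(edge_density(a), 10400 / (300 * 299))
  # interpartition: each cross edge counted once over cross pairs
  ip <- scope_subgraph(a, 50, "interpartition")
  m_cross <- sum(ip) / 2
  expect_equal(edge_density(ip, cross_sizes = c(50, 250)), m_cross / (50 * 250))
})

test_that("global clustering matches closed forms and brute-force counting", {
  expect_equal(global_clustering(complete_graph(4)), 1.0)
  expect_equal(global_clustering(star_graph(4)), 0.0)
  tri_pend <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  expect_equal(global_clustering(tri_pend), 0.6)
  set.seed(3)
  for (rep in 1:20) {
    a <- random_graph(12, sample(8:30, 1))
    # trace formula
    a2 <- a %*% a; a3 <- a2 %*% a
    denom <- sum(a2) - sum(diag(a2))
    trace_val <- if (denom == 0) 0 else sum(diag(a3)) / denom
    expect_equal(global_clustering(a), clustering_brute(a), tolerance = 1e-12)
    expect_equal(global_clustering(a), trace_val, tolerance = 1e-12)
  }
})

test_that("average path length uses the zero convention for unreachable pairs", {
  expect_equal(avg_path_length(complete_graph(3)), 1.0)
  expect_equal(avg_path_length(path_graph(3)), 8 / 6)
  k2_iso <- adj_from_edges(3, list(c(1, 2)))
  expect_equal(avg_path_length(k2_iso), 2 / 6)
  set.seed(4)
  for (rep in 1:10) {
    a <- random_graph(10, sample(5:20, 1))
    expect_equal(avg_path_length(a), path_length_brute(a), tolerance = 1e-12)
  }
})

test_that("small-world index is the clustering to path-length ratio", {
  expect_equal(small_world(1, 1), 1.0)
  expect_equal(small_world(0.6, 1.25), 0.48)
  expect_true(is.na(small_world(0.5, 0)))
})

test_that("fast-greedy modularity matches closed forms and never beats the optimum", {
  two_k3 <- adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                   c(4, 5), c(5, 6), c(4, 6)))
  r <- graph_modularity(two_k3)
  expect_equal(r$Q, 0.5)
  expect_equal(length(unique(r$membership)), 2)
  expect_equal(graph_modularity(complete_graph(5))$Q, 0.0)
  expect_error(graph_modularity(matrix(0L, 4, 4)), "edgeless")
  # two K4s joined by one edge: greedy finds the obvious split, which is
  # also the exhaustive-partition optimum
  two_k4 <- adj_from_edges(8, list(c(1,2),c(1,3),c(1,4),c(2,3),c(2,4),c(3,4),
                                   c(5,6),c(5,7),c(5,8),c(6,7),c(6,8),c(7,8),
                                   c(4,5)))
  best <- modularity_exhaustive(two_k4)
  expect_equal(graph_modularity(two_k4)$Q, best, tolerance = 1e-12)
  set.seed(6)
  for (rep in 1:5) {
    a <- random_graph(8, sample(7:16, 1))
    if (sum(a) == 0) next
    expect_lte(graph_modularity(a)$Q, modularity_exhaustive(a) + 1e-12)
  }
})

test_that("degree assortativity matches closed forms and flags regular graphs", {
  expect_equal(degree_assortativity(path_graph(3)), -1.0)
  expect_equal(degree_assortativity(star_graph(6)), -1.0)
  expect_true(is.na(degree_assortativity(complete_graph(4))))
})

test_that("partition scopes are induced subgraphs plus the cross-edge set", {
  set.seed(7)
  a <- random_graph(60, 250)
  mino <- scope_subgraph(a, 10, "minority")
  majo <- scope_subgraph(a, 10, "majority")
  ip <- scope_subgraph(a, 10, "interpartition")
  expect_equal(dim(mino), c(10, 10))
  expect_equal(dim(majo), c(50, 50))
  expect_identical(mino, a[1:10, 1:10])
  # edge partition identity: scopes tile the whole edge set
  expect_equal(sum(mino) / 2 + sum(majo) / 2 + sum(ip) / 2, 250)
  expect_true(all(ip[1:10, 1:10] == 0))
  expect_true(all(ip[11:60, 11:60] == 0))
})

test_that("rich-club profile matches closed forms on complete and small graphs", {
  set.seed(8)
  k5 <- complete_graph(5)
  rc <- rich_club(k5, null_count = 20)
  expect_true(all(rc$rc_raw[rc$k <= 4] == 1))
  expect_true(all(rc$rc_norm[!is.na(rc$rc_norm)] == 1))  # nulls == input
  tri_pend <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  rc2 <- rich_club(tri_pend, null_count = 10)
  expect_equal(rc2$rc_raw[rc2$k == 2], 1.0)  # the induced triangle
  expect_equal(rc2$n_club, c(4L, 3L, 1L))
  expect_true(all(is.na(rc2$rc_raw[rc2$k == 3])))  # club of one node
  # club membership is non-increasing in k
  expect_true(all(diff(rc2$n_club) <= 0))
})

test_that("rich-club nulls preserve the degree sequence and flag real clubs", {
  set.seed(9)
  # planted rich club: K6 core loosely attached to a sparse periphery
  a <- matrix(0L, 30, 30)
  a[1:6, 1:6] <- 1L; diag(a) <- 0L
  for (i in 7:30) { j <- sample(1:6, 1); a[i, j] <- a[j, i] <- 1L }
  for (e in 1:10) { ij <- sample(7:30, 2); a[ij[1], ij[2]] <- a[ij[2], ij[1]] <- 1L }
  rc <- rich_club(a, null_count = 60)
  expect_gt(max(rc$rc_norm[rc$n_club == 6], na.rm = TRUE), 1)
})

test_that("baseline normalization divides by ensemble means, sparing assortativity", {
  set.seed(10)
  a <- random_graph(40, 120)
  series <- cbind(attempt = 0, network_metrics(a, 10))
  base <- list(whole = baseline_metric_means(40, 120, 20))
  norm <- normalize_metrics(series, base)
  w <- series$scope == "whole"
  expect_equal(norm$assortativity[w], series$assortativity[w])
  expect_equal(norm$clustering[w],
               series$clustering[w] / base$whole[["clustering"]])
  # a metric equal to its baseline mean normalizes to 1
  series2 <- series
  series2$clustering[w] <- base$whole[["clustering"]]
  expect_equal(normalize_metrics(series2, base)$clustering[w], 1.0)
  # self-normalization: a fresh random graph sits near 1 within spread
  expect_gt(norm$clustering[w], 0.3); expect_lt(norm$clustering[w], 3)
})
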