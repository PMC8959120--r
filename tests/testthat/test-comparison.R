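test_that("functional connectivity is the absolute activation difference", {
  f <- functional_connectivity(c(0.1, 0.4))
  expect_equal(f[1, 2], 0.3)
  set.seed(21)
  x <- runif(8)
  f <- functional_connectivity(x)
  expect_true(all(diag(f) == 0))
  expect_identical(f, t(f))
  expect_equal(functional_connectivity(x + 0.17), f)  # shift invariance
})

test_that("functional graphs keep the most similar pairs at the edge budget", {
  n <- 4
  f <- functional_connectivity(c(0.0, 0.10, 0.25, 0.45))
  all_pairs <- n * (n - 1) / 2
  expect_equal(sum(functional_graph(f, all_pairs)) / 2, all_pairs)
  expect_equal(sum(functional_graph(f, 0)), 0)
  g2 <- functional_graph(f, 2)
  # two smallest differences: (1,2) = 0.10 and (2,3) = 0.15
  expect_equal(g2[1, 2], 1L)
  expect_equal(g2[2, 3], 1L)
  expect_equal(sum(g2) / 2, 2)
})

test_that("NetSimile signatures are fixed-length, label-invariant aggregates", {
  c5 <- adj_from_edges(5, list(c(1,2), c(2,3), c(3,4), c(4,5), c(5,1)))
  sig <- netsimile_signature(c5)
  expect_length(sig, 35)
  expect_true(all(is.finite(sig)))
  expect_true(all(sig[grepl("_sd$", names(sig))] == 0))  # vertex-transitive
  k4 <- complete_graph(4)
  sk <- netsimile_signature(k4)
  expect_equal(unname(sk[c("degree_median", "degree_mean", "degree_sd")]),
               c(3, 3, 0))
  # isomorphic graphs give identical signatures
  set.seed(23)
  a <- random_graph(12, 25)
  p <- sample(12)
  expect_equal(netsimile_signature(a[p, p]), netsimile_signature(a))
})

test_that("Canberra distance between signatures behaves as a pseudo-metric", {
  expect_equal(netsimile_distance(c(1, 0), c(0, 1)), 2.0)
  set.seed(24)
  for (rep in 1:20) {
    a <- runif(10); b <- runif(10); c <- runif(10)
    expect_equal(netsimile_distance(a, a), 0)
    expect_equal(netsimile_distance(a, b), netsimile_distance(b, a))
    expect_gte(netsimile_distance(a, b), 0)
    expect_lte(netsimile_distance(a, c),
               netsimile_distance(a, b) + netsimile_distance(b, c) + 1e-12)
  }
})

test_that("HHG finds dependence for identical samples and stays in [0,1]", {
  set.seed(25)
  fa <- matrix(runif(30), 15, 2)
  r <- hhg_test(fa, fa, n_permutations = 99)
  expect_equal(r$p_value, 1 / 100)  # minimal attainable p
  fb <- matrix(runif(30), 15, 2)
  r2 <- hhg_test(fa, fb, n_permutations = 49)
  expect_gte(r2$p_value, 0); expect_lte(r2$p_value, 1)
  expect_error(hhg_test(fa[1:2, , drop = FALSE], fb[1:2, , drop = FALSE]),
               "at least 3")
})

test_that("HHG permutation null rejects at the nominal rate under independence", {
  set.seed(26)
  reps <- 200
  rejections <- 0
  for (r in 1:reps) {
    fa <- matrix(runif(24), 12, 2)
    fb <- matrix(runif(24), 12, 2)
    p <- hhg_test(fa, fb, n_permutations = 99)$p_value
    if (p <= 0.05) rejections <- rejections + 1
  }
  # binomial(200, 0.05): mean 10, sd ~3.1; allow 4 sd
  expect_gte(rejections, 1)
  expect_lte(rejections, 23)
})

test_that("dissimilarity matrices are symmetric, hollow and max-normalized", {
  set.seed(27)
  graphs <- lapply(1:4, function(i) random_graph(14, 30))
  names(graphs) <- paste0("g", 1:4)
  d <- dissimilarity_matrix(graphs, method = "netsimile")
  expect_identical(unclass(d[1:4, 1:4]), t(unclass(d[1:4, 1:4])))
  expect_true(all(diag(d) == 0))
  expect_equal(max(d), 1)
  expect_true(all(d >= 0 & d <= 1))
  dh <- dissimilarity_matrix(graphs, method = "hhg", n_permutations = 19)
  expect_true(all(dh[upper.tri(dh)] > 0 & dh[upper.tri(dh)] <= 1))
})

test_that("family contrast averages blocks with their true sizes", {
  fams <- c("A", "A", "B", "B", "B")
  d <- matrix(0.5, 5, 5); diag(d) <- 0
  ct <- family_contrast(d, fams)
  # within-A block: 2x2 with zero diagonal -> mean = 2*0.5/4
  expect_equal(ct["A", "A"], 0.25)
  expect_equal(ct["A", "B"], 0.5)
  expect_equal(ct["B", "B"], (6 * 0.5) / 9)
  # block sums recompose the full matrix sum
  sizes <- table(fams)
  total <- sum(vapply(rownames(ct), function(fi)
    sum(vapply(colnames(ct), function(fj)
      ct[fi, fj] * sizes[[fi]] * sizes[[fj]], 0)), 0))
  expect_equal(total, sum(d))
})

test_that("differentiation scores ratio within to between resemblance", {
  ct <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(unname(differentiation_scores(ct)), c(2, 2))  # 1/(1-0.5)
  ct2 <- matrix(0.3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(differentiation_scores(ct2)), rep(1, 3))
})

test_that("composite matrices pack HHG below and NetSimile above the diagonal", {
  ns <- matrix(1:16 / 16, 4, 4); hh <- matrix(16:1 / 16, 4, 4)
  cp <- composite_dissimilarity(ns, hh)
  expect_equal(cp[1, 2], ns[1, 2])
  expect_equal(cp[2, 1], hh[2, 1])
  expect_true(all(diag(cp) == 0))
  expect_equal(cp[upper.tri(cp)], ns[upper.tri(ns)])
  expect_equal(cp[lower.tri(cp)], hh[lower.tri(hh)])
})
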