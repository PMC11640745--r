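# Weighted centralities and edge-weight entropy.

path_graph <- function(w12 = 1, w23 = 1) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w12
  W[2, 3] <- W[3, 2] <- w23
  W
}

test_that("degree, closeness and betweenness match hand calculations on tiny graphs", {
  P <- path_graph()
  expect_equal(unname(weighted_degree(P)), c(1, 2, 1))
  D <- weighted_shortest_paths(P)
  expect_equal(D[1, 3], 2)
  expect_equal(unname(closeness_w(P)), c(1 / 3, 1 / 2, 1 / 3), ignore_attr = TRUE)
  expect_equal(unname(betweenness_w(P)), c(0, 1, 0))
  # single edge of weight 0.5 has distance 1/0.5
  E1 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(weighted_shortest_paths(E1)[1, 2], 2)
  # star with 3 leaves: center 1/3, leaf 1/(1 + 2 + 2)
  S <- make_fixture_network("star", 4)
  expect_equal(unname(closeness_w(S)), c(1 / 3, 0.2, 0.2, 0.2), ignore_attr = TRUE)
  # uniform K4: all degrees 3, all betweenness 0 (each pair adjacent)
  K4 <- make_fixture_network("uniform", 4)
  expect_equal(unname(weighted_degree(K4)), rep(3, 4))
  expect_equal(unname(betweenness_w(K4)), rep(0, 4))
})

test_that("shortest paths and betweenness match brute-force oracles on random graphs", {
  for (seed in c(2, 5, 9)) {
    W <- make_fixture_network("random", 8, seed = seed)
    W[W < 0.3] <- 0   # induce some sparsity
    expect_equal(unname(weighted_shortest_paths(W)), brute_shortest_paths(W),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(betweenness_w(W)), brute_betweenness(W), tolerance = 1e-8)
  }
})

test_that("eigenvector centrality matches the dense eigendecomposition", {
  # two nodes, one edge of weight w: equal centralities, lambda = w
  E1 <- matrix(c(0, 0.7, 0.7, 0), 2)
  v <- eigenvector_w(E1)
  expect_equal(unname(v), rep(1 / sqrt(2), 2), ignore_attr = TRUE)
  expect_equal(attr(v, "lambda"), 0.7)
  # star: hub strictly largest
  S <- make_fixture_network("star", 5)
  vs <- eigenvector_w(S)
  expect_true(vs[1] > max(vs[-1]))
  # random graphs vs eigen()
  for (seed in c(3, 8)) {
    W <- make_fixture_network("random", 10, seed = seed)
    v <- eigenvector_w(W)
    es <- eigen(W, symmetric = TRUE)
    ref <- abs(es$vectors[, which.max(es$values)])
    expect_equal(unname(v), ref, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
    expect_equal(unname(drop(W %*% v)), unname(attr(v, "lambda") * v),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("edge-weight entropy follows the normalised weight distribution", {
  K <- make_fixture_network("uniform", 4)  # 6 equal edges
  expect_equal(edge_weight_entropy(K), log(6))
  E1 <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(edge_weight_entropy(E1), 0)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[1, 3] <- W[3, 1] <- 1; W[2, 3] <- W[3, 2] <- 2
  expect_equal(edge_weight_entropy(W), -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_error(edge_weight_entropy(matrix(0, 3, 3)), "empty")
  # maximal iff equal; concentrating mass strictly lowers it
  ent <- sapply(seq(0, 0.8, by = 0.2), function(a) {
    W2 <- make_fixture_network("uniform", 4)
    W2[1, 2] <- W2[2, 1] <- 1 + a * 5
    edge_weight_entropy(W2)
  })
  expect_true(all(diff(ent) < 0))
  expect_equal(max(ent), log(6))
})

test_that("metrics are permutation-equivariant", {
  W <- make_fixture_network("random", 7, seed = 13)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  Wp <- W[perm, perm]
  expect_equal(unname(weighted_degree(Wp)), unname(weighted_degree(W))[perm])
  expect_equal(unname(closeness_w(Wp)), unname(closeness_w(W))[perm], ignore_attr = TRUE)
  expect_equal(unname(betweenness_w(Wp)), unname(betweenness_w(W))[perm], tolerance = 1e-10)
  expect_equal(unname(eigenvector_w(Wp)), unname(eigenvector_w(W))[perm],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(edge_weight_entropy(Wp), edge_weight_entropy(W))
})

test_that("node-metric means aggregate the table and handle disconnection", {
  P <- path_graph()
  nm <- node_metrics(P, source = "full")
  mm <- node_metric_means(nm)
  expect_equal(unname(mm["mean_betweenness"]), 1 / 3)
  expect_true(all(mm >= apply(nm[, 2:5], 2, min) - 1e-12))
  # disconnected graph: closeness within components, flagged
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 0.5
  nm2 <- node_metrics(W, source = "full")
  expect_true(attr(nm2, "disconnected"))
  expect_equal(nm2$closeness, c(1, 1, 0.5, 0.5))
})
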