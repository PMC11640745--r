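# Information-theoretic descriptors: probabilities, entropy, Phi, complexity.

test_that("edge probabilities normalise to one and match tiny examples", {
  W <- matrix(c(0, 2, 2, 0), 2)
  p <- edge_probability_distribution(W)
  expect_equal(p[1, 2], 0.5)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  K3 <- make_fixture_network("uniform", 3)
  p3 <- edge_probability_distribution(K3)
  expect_true(all(abs(p3[p3 > 0] - 1 / 6) < 1e-12))
  W5 <- make_fixture_network("random", 5, seed = 1)
  expect_equal(sum(edge_probability_distribution(W5)), 1, tolerance = 1e-12)
  expect_error(edge_probability_distribution(matrix(0, 3, 3)), "all-zero")
})

test_that("network entropy follows the ordered-cell convention", {
  W <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(network_entropy(edge_probability_distribution(W)), log(2))
  K3 <- make_fixture_network("uniform", 3)
  expect_equal(network_entropy(edge_probability_distribution(K3)), log(6))
  # ordered-cell entropy exceeds the per-edge entropy by exactly log 2
  W5 <- make_fixture_network("random", 5, seed = 6)
  expect_equal(network_entropy(edge_probability_distribution(W5)),
               edge_weight_entropy(W5) + log(2), tolerance = 1e-12)
})

test_that("binarisation keeps cells at or above the threshold fraction of the maximum", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.25; p[1, 3] <- p[3, 1] <- 0.15; p[2, 3] <- p[3, 2] <- 0.1
  b1 <- binarize_probability(p, theta = 1)
  expect_equal(sum(b1), 2)  # only the maximal symmetric pair survives
  ball <- binarize_probability(p, theta = 0.001)
  expect_equal(sum(ball), 6)
  # pattern {1.0, 0.6, 0.3} * pmax at theta = 0.5 keeps the first two pairs
  p2 <- matrix(0, 4, 4)
  p2[1, 2] <- p2[2, 1] <- 0.2
  p2[1, 3] <- p2[3, 1] <- 0.12
  p2[1, 4] <- p2[4, 1] <- 0.06
  b2 <- binarize_probability(p2 / sum(p2), theta = 0.5)
  expect_equal(b2[1, 2], 1); expect_equal(b2[1, 3], 1); expect_equal(b2[1, 4], 0)
  expect_true(all(diag(binarize_probability(diag(3) * 0 + 0.1)) == 0))
  expect_error(binarize_probability(p, theta = 0), "theta")
})

test_that("subsystem information counts within-subset edges", {
  b <- matrix(0, 4, 4)
  b[1, 2] <- b[2, 1] <- 1
  b[3, 4] <- b[4, 3] <- 1
  b[1, 3] <- b[3, 1] <- 1
  expect_equal(subsystem_information(b, c(1, 2)), 0)        # single edge
  expect_equal(subsystem_information(b, c(1, 2, 3)), log(2)) # two edges
  expect_equal(subsystem_information(b, c(2, 4)), 0)        # empty subsystem
  expect_equal(subsystem_information(b, 1:4), log(3))       # whole graph
  expect_error(subsystem_information(b, integer(0)), "nonempty")
})

test_that("a single-edge graph has identically zero integrated information", {
  b <- matrix(0, 5, 5)
  b[1, 2] <- b[2, 1] <- 1
  est <- estimate_phi(b, n_samples = 500, seed = 2)
  expect_identical(est$phi, 0)
  expect_identical(exhaustive_phi(b)$phi, 0)
})

test_that("the sampled estimator is deterministic and unbiased for the exhaustive mean", {
  W <- make_fixture_network("random", 6, seed = 9)
  b <- binarize_probability(edge_probability_distribution(W), theta = 0.4)
  e1 <- estimate_phi(b, n_samples = 1000, seed = 5)
  e2 <- estimate_phi(b, n_samples = 1000, seed = 5)
  expect_identical(e1$phi, e2$phi)
  ex <- exhaustive_phi(b)
  ests <- lapply(1:12, function(s) estimate_phi(b, n_samples = 1000, seed = s))
  mean_est <- mean(vapply(ests, `[[`, numeric(1), "phi"))
  pooled_se <- sqrt(mean(vapply(ests, `[[`, numeric(1), "se")^2) / 12)
  expect_lt(abs(mean_est - ex$phi), 3 * pooled_se)
})

test_that("the exhaustive oracle enumerates the right number of bipartitions", {
  b <- make_fixture_network("uniform", 3)
  expect_equal(exhaustive_phi(b)$n_samples, 3)
  b4 <- make_fixture_network("uniform", 4)
  expect_equal(exhaustive_phi(b4)$n_samples, 7)
  expect_error(exhaustive_phi(matrix(0, 15, 15)), "n > 14")
})

test_that("disequilibrium and complexity satisfy their identities", {
  # one unit cell on a 2x2 grid
  p <- matrix(c(0, 1, 0, 0), 2)
  expect_equal(disequilibrium(p), sqrt((1 - 0.25)^2 + 3 * 0.25^2))
  # a genuinely uniform synthetic matrix has zero disequilibrium
  u <- matrix(1 / 9, 3, 3)
  expect_equal(disequilibrium(u), 0)
  expect_equal(statistical_complexity(1.7, 0), 0)
  expect_equal(statistical_complexity(log(2), 0.5), log(2) * 0.5)
  # C / H = D wherever H > 0, and the coarse bound holds
  W <- make_fixture_network("random", 6, seed = 4)
  pm <- edge_probability_distribution(W)
  H <- network_entropy(pm); D <- disequilibrium(pm)
  C <- statistical_complexity(H, D)
  expect_equal(C / H, D)
  expect_lte(D, sqrt(1 + 1 / 36))
})
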