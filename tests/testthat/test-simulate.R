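# Synthetic generators: pair simulator, cohort builder, fixture networks.

test_that("pair simulator is deterministic and rejects non-stationary truths", {
  tr <- nardl_truth()
  a <- simulate_nardl_pair(tr, n = 200, seed = 11)
  b <- simulate_nardl_pair(tr, n = 200, seed = 11)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  c <- simulate_nardl_pair(tr, n = 200, seed = 12)
  expect_false(identical(a$y, c$y))
  expect_error(nardl_truth(phi = c(0.7, 0.4), bpos = c(0, 0, 0), bneg = c(0, 0, 0)),
               "sum\\(phi\\)")
  expect_error(nardl_truth(sigma = 0), "sigma")
})

test_that("a decoupled pair produces uncorrelated series", {
  tr <- nardl_truth(phi = c(1e-9, 0), bpos = c(0, 0, 0), bneg = c(0, 0, 0), sigma = 1)
  sim <- simulate_nardl_pair(tr, n = 4000, seed = 21)
  expect_lt(abs(cor(sim$x, sim$y)), 0.05)
  expect_lt(abs(cor(sim$x[-4000], sim$y[-1])), 0.05)
})

test_that("an instantaneous positive-branch coupling is recovered by regression", {
  tr <- nardl_truth(phi = c(1e-9, 0), bpos = c(0.8, 0, 0), bneg = c(0, 0, 0), sigma = 1)
  sim <- simulate_nardl_pair(tr, n = 2000, seed = 2)
  ps <- decompose_partial_sums(sim$x)
  slope <- coef(lm(sim$y[-1] ~ ps$pos + ps$neg))[["ps$pos"]]
  expect_lt(abs(slope - 0.8), 0.05)
})

test_that("cohort shape contract and determinism hold", {
  spec <- cohort_spec(n_hc = 5, n_pd = 5, n_rois = 6, n_time = 300, seed = 3)
  coh <- simulate_cohort(spec)
  expect_length(coh$subjects, 10)
  expect_true(all(vapply(coh$subjects, function(s) all(dim(s$series) == c(300, 6)), logical(1))))
  expect_true(all(vapply(coh$subjects, function(s) all(is.finite(s$series)), logical(1))))
  expect_equal(coh$manifest$group, rep(c("HC", "PD"), c(5, 5)))
  coh2 <- simulate_cohort(spec)
  expect_identical(coh$subjects[[4]]$series, coh2$subjects[[4]]$series)
  # patient truths are attenuated relative to controls
  expect_true(all(abs(coh$truth$pd$bpos) <= abs(coh$truth$hc$bpos)))
  expect_gte(coh$truth$pd$sigma, coh$truth$hc$sigma)
  expect_error(cohort_spec(n_hc = 1), "n_hc")
  expect_error(cohort_spec(n_rois = 2), "n_rois")
})

test_that("fixture networks have the documented structure", {
  u <- make_fixture_network("uniform", 4)
  expect_equal(sum(u[upper.tri(u)] == 1), 6)
  st <- make_fixture_network("star", 4)
  nz <- which(upper.tri(st) & st > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 3)
  expect_true(all(nz[, 1] == 1))
  r1 <- make_fixture_network("random", 7, seed = 5)
  r2 <- make_fixture_network("random", 7, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 1) && all(diag(r1) == 0) && isTRUE(all.equal(r1, t(r1))))
  rg <- make_fixture_network("ring", 5)
  expect_equal(rowSums(rg > 0), setNames(rep(2, 5), rownames(rg)))
  expect_error(make_fixture_network("banana", 4))
})

test_that("cohorts round-trip through the delimited-text layout", {
  dir <- tempfile("cohort")
  coh <- simulate_cohort(cohort_spec(n_hc = 2, n_pd = 2, n_rois = 4, n_time = 60,
                                     lag_order = 1, seed = 8))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(back$manifest$group, coh$manifest$group)
  expect_equal(back$subjects[[2]]$series, coh$subjects[[2]]$series,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colnames(back$subjects[[1]]$series), colnames(coh$subjects[[1]]$series))
})
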