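# SMOTE balancing and the group statistical battery.

test_that("SMOTE balances classes with synthetic rows on minority segments", {
  set.seed(3)
  X <- rbind(matrix(rnorm(20 * 3), 20, 3), matrix(rnorm(60 * 3, 2), 60, 3))
  y <- rep(c("HC", "PD"), c(20, 60))
  sm <- smote(X, y, k = 5, seed = 9)
  expect_equal(as.integer(table(sm$y)), c(60L, 60L))
  expect_equal(sum(sm$synthetic), 40)
  # every synthetic row lies on the segment between its base and neighbour
  syn <- which(sm$synthetic)
  for (s in syn) {
    base <- X[sm$base_index[s], ]
    nb <- X[sm$neighbor_index[s], ]
    diffv <- nb - base
    lam <- if (any(diffv != 0)) ((sm$X[s, ] - base) / diffv)[which(diffv != 0)[1]] else 0
    expect_equal(sm$X[s, ], base + lam * diffv, tolerance = 1e-10)
    expect_gte(lam, 0); expect_lte(lam, 1)
  }
  # and inside the minority bounding box
  lo <- apply(X[1:20, ], 2, min); hi <- apply(X[1:20, ], 2, max)
  expect_true(all(t(sm$X[syn, ]) >= lo - 1e-12) && all(t(sm$X[syn, ]) <= hi + 1e-12))
})

test_that("a forced midpoint interpolation reproduces the midpoint", {
  X <- rbind(c(0, 0), c(1, 1), matrix(5, 3, 2))
  y <- c("a", "a", "b", "b", "b")
  sm <- smote(X, y, k = 1, seed = 1, delta = 0.5)
  expect_true(any(apply(sm$X[sm$synthetic, , drop = FALSE], 1,
                        function(r) all(r == c(0.5, 0.5)))))
  expect_equal(as.integer(table(sm$y)), c(3L, 3L))
})

test_that("k is reduced with a warning when the minority class is tiny", {
  X <- rbind(matrix(0:5 / 5, 3, 2), matrix(5, 8, 2) + rnorm(16, 0, 0.1))
  y <- rep(c("a", "b"), c(3, 8))
  expect_warning(sm <- smote(X, y, k = 5, seed = 2), "k reduced")
  expect_equal(sm$k, 2)
  expect_equal(as.integer(table(sm$y)), c(8L, 8L))
})

test_that("the Mann-Whitney U statistic matches brute-force pair counting", {
  expect_equal(brute_mw_u(c(1, 2), c(3, 4)), 0)
  suppressWarnings({
    rep1 <- run_group_tests(cbind(f = c(1, 2, 5, 3, 4, 6)),
                            rep(c("g1", "g2"), each = 3))
  })
  expect_equal(rep1$mann_whitney$U, brute_mw_u(c(1, 2, 5), c(3, 4, 6)))
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:12, sample(3:8, 1), replace = TRUE)  # allows ties
    y <- sample(1:12, sample(3:8, 1), replace = TRUE)
    suppressWarnings(rep2 <- run_group_tests(cbind(f = c(x, y)),
                                             rep(c("a", "b"), c(length(x), length(y)))))
    expect_equal(rep2$mann_whitney$U, brute_mw_u(x, y))
  }
})

test_that("exact small-sample p-values and the effect size follow their formulas", {
  suppressWarnings({
    r <- run_group_tests(cbind(f = c(1, 2, 3, 4, 30, 40)), rep(c("a", "b"), each = 3))
  })
  # U = 0 here; rank-biserial r = 1 - 2U/(n1 n2)
  expect_equal(r$mann_whitney$effect_size, 1)
  # two vs two: exact two-sided p for complete separation is 1/3
  wt <- suppressWarnings(stats::wilcox.test(c(1, 2), c(3, 4), exact = TRUE))
  expect_equal(wt$p.value, 1 / 3, tolerance = 1e-12)
  # near-identical groups give a near-zero effect size
  suppressWarnings({
    r0 <- run_group_tests(cbind(f = c(1, 2, 3, 4, 1.01, 2.01, 3.01, 4.01)),
                          rep(c("a", "b"), each = 4))
  })
  expect_lt(abs(r0$mann_whitney$effect_size), 0.3)
  expect_true(all(abs(r$mann_whitney$effect_size) <= 1))
})

test_that("Bonferroni adjustment multiplies by the feature count and caps at one", {
  set.seed(5)
  X <- matrix(rnorm(20 * 7), 20, 7, dimnames = list(NULL, paste0("f", 1:7)))
  y <- rep(c("a", "b"), each = 10)
  r <- run_group_tests(X, y)
  expect_equal(r$mann_whitney$p_bonferroni, pmin(1, 7 * r$mann_whitney$p))
  expect_true(all(r$mann_whitney$p_bonferroni >= r$mann_whitney$p))
  expect_equal(pmin(1, 7 * 0.01), 0.07)
})

test_that("constant features are flagged rather than tested", {
  X <- cbind(f1 = rnorm(12), f2 = rep(1, 12))
  y <- rep(c("a", "b"), each = 6)
  expect_warning(r <- run_group_tests(X, y), "zero-variance")
  expect_true(r$mann_whitney$constant[2])
  expect_true(is.na(r$mann_whitney$p[2]))
  expect_false(r$mann_whitney$constant[1])
})

test_that("feature correlations behave as Pearson correlation should", {
  set.seed(11)
  x <- rnorm(50)
  C <- feature_correlations(cbind(a = x, b = 2 * x, c = rnorm(50)))
  expect_equal(diag(C), c(a = 1, b = 1, c = 1))
  expect_equal(C["a", "b"], 1)
  expect_equal(C, t(C))
  # independent features: negligible correlation at n = 1000
  ok <- vapply(1:10, function(s) {
    set.seed(s)
    M <- feature_correlations(matrix(rnorm(1000 * 3), 1000, 3))
    max(abs(M[upper.tri(M)])) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("the pre/post-SMOTE battery wrapper emits both reports", {
  set.seed(13)
  X <- rbind(matrix(rnorm(8 * 7), 8, 7), matrix(rnorm(24 * 7, 0.5), 24, 7))
  colnames(X) <- paste0("f", 1:7)
  y <- rep(c("HC", "PD"), c(8, 24))
  gb <- group_battery(X, y, k = 3, seed = 2)
  expect_s3_class(gb$pre_smote, "group_stat_report")
  expect_s3_class(gb$post_smote, "group_stat_report")
  expect_equal(gb$pre_smote$n, c(8, 24))
  expect_equal(gb$post_smote$n, c(24, 24))
})
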