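# Partial-sum decomposition, the NARDL fit and the combined-dependency score.

test_that("partial-sum decomposition matches direct arithmetic in both modes", {
  x <- c(0, 1, -1, 2)
  inc <- decompose_partial_sums(x, "increment")
  expect_equal(inc$pos, c(1, 0, 3))
  expect_equal(inc$neg, c(0, -2, 0))
  cum <- decompose_partial_sums(x, "cumulative")
  expect_equal(cum$pos, c(1, 1, 4))
  expect_equal(cum$neg, c(0, -2, -2))
  # reconstruction identities
  expect_equal(inc$pos + inc$neg, diff(x))
  expect_equal(cum$pos + cum$neg, x[-1] - x[1])
  # monotone series has an all-zero negative branch
  mono <- decompose_partial_sums(sort(rnorm(20)))
  expect_true(all(mono$neg == 0))
  # constant series is legal with both branches zero
  cst <- decompose_partial_sums(rep(2, 5))
  expect_true(all(cst$pos == 0) && all(cst$neg == 0))
})

test_that("combined dependency arithmetic follows the short/long-run identities", {
  dep <- nardl_cd(phi = 0.5, bpos = 0.6, bneg = -0.2)
  expect_equal(dep$lp, 1.2)
  expect_equal(dep$ln, -0.4)
  expect_equal(dep$cd, (0.6 + 1.2) - (-0.2 + -0.4))
  # literal printed form differs by the sign of the negative aggregate
  lit <- nardl_cd(phi = 0.5, bpos = 0.6, bneg = -0.2, cd_form = "literal")
  expect_equal(lit$cd, 0.6 + 1.2 - (-0.2) + (-0.4))
  # near-unit-root autoregression is floored and flagged
  fl <- nardl_cd(phi = c(0.9995, 0.0004), bpos = c(1, 0, 0), bneg = c(0, 0, 0))
  expect_true(fl$longrun_flagged)
  expect_lte(abs(fl$lp), 1e3)
})

test_that("the fit recovers generating coefficients on long series", {
  tr <- nardl_truth(phi = c(0.3, 0.1), bpos = c(0.4, 0.1, 0), bneg = c(-0.2, 0, 0.1))
  truth_vec <- c(0, tr$phi, tr$bpos, tr$bneg)
  errs <- sapply(1:10, function(s) {
    sim <- simulate_nardl_pair(tr, n = 2000, seed = 100 + s)
    coef(nardl(sim$y, sim$x, p = 2)) - truth_vec
  })
  expect_lt(max(apply(abs(errs), 1, median)), 0.05)
})

test_that("independent white-noise response gives near-zero coefficients", {
  # per-coefficient calibration: each estimate lies within +/- 0.08 of zero in
  # at least 95% of draws (about a 2-sigma band at this sample size)
  absvals <- sapply(1:20, function(s) {
    set.seed(s)
    x <- as.numeric(stats::arima.sim(list(ar = 0.5), 2000))
    abs(coef(nardl(rnorm(2000), x, p = 2)))
  })
  expect_gte(mean(absvals < 0.08), 0.95)
  expect_lt(max(apply(absvals, 1, median)), 0.05)
})

test_that("the fit equals a hand-rolled normal-equations solve to high precision", {
  set.seed(42)
  n <- 30
  x <- cumsum(rnorm(n))
  y <- 0.2 + 0.4 * c(0, head(x, -1)) + rnorm(n)
  p <- 1
  fit <- nardl(y, x, p = p)
  # oracle: build the design by hand and solve the normal equations
  ps <- decompose_partial_sums(x)
  tt <- (p + 2):n
  X <- cbind(1, y[tt - 1], ps$pos[tt - 1], ps$pos[tt - 2], ps$neg[tt - 1], ps$neg[tt - 2])
  beta <- solve(crossprod(X), crossprod(X, y[tt]))
  expect_equal(unname(coef(fit)[c("alpha", "phi1", "bpos0", "bpos1", "bneg0", "bneg1")]),
               drop(beta), tolerance = 1e-10)
})

test_that("a constant driver yields a flagged degenerate fit with CD = 0", {
  set.seed(7)
  fit <- nardl(rnorm(100), rep(3, 100), p = 2)
  expect_true(fit$degenerate)
  expect_identical(fit$cd, 0)
  expect_true(all(is.na(coef(fit))))
})

test_that("generated series satisfy the recurrence exactly when innovations are replayed", {
  tr <- nardl_truth(phi = c(0.3, 0.1), bpos = c(0.8, 0.3, 0), bneg = c(-0.5, 0, -0.2))
  sim <- simulate_nardl_pair(tr, n = 300, seed = 9)
  ps <- decompose_partial_sums(sim$x)
  p <- tr$p
  tt <- (p + 2):300
  recon <- tr$alpha + sim$eps[tt]
  for (i in 1:p) recon <- recon + tr$phi[i] * sim$y[tt - i]
  for (i in 0:p) {
    recon <- recon + tr$bpos[i + 1] * ps$pos[tt - i - 1] +
      tr$bneg[i + 1] * ps$neg[tt - i - 1]
  }
  expect_equal(recon, sim$y[tt], tolerance = 1e-12)
})

test_that("model methods are coherent (predict, residuals, summary, simulate)", {
  tr <- nardl_truth()
  sim <- simulate_nardl_pair(tr, n = 400, seed = 3)
  fit <- nardl(sim$y, sim$x, p = 2)
  expect_equal(predict(fit, sim$y, sim$x), fitted(fit))
  expect_equal(fitted(fit) + residuals(fit), sim$y[4:400])
  sm <- summary(fit)
  expect_equal(unname(sm$coef_table[, "Estimate"]), unname(coef(fit)))
  re <- simulate(fit, nsim = 2, seed = 5, n = 120)
  expect_length(re, 2)
  expect_length(re[[1]]$y, 120)
})
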