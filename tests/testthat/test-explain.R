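# Exact Shapley attribution and the LIME surrogate.

test_that("exact Shapley recovers the closed form for a linear model", {
  set.seed(3)
  beta <- c(2, -1, 0.5, 0, 1.5)
  f <- function(X) drop(X %*% beta)
  bg <- matrix(rnorm(40 * 5), 40, 5)
  x <- rnorm(5)
  ex <- exact_shapley(f, x, bg)
  expect_equal(unname(ex$phi), beta * (x - colMeans(bg)), tolerance = 1e-10)
  expect_lt(ex$efficiency_gap, 1e-10)
})

test_that("Shapley efficiency and symmetry hold for a nonlinear model", {
  set.seed(4)
  f <- function(X) 1 / (1 + exp(-(X[, 1] * X[, 2] + X[, 3]^2)))
  bg <- matrix(rnorm(30 * 3), 30, 3)
  x <- c(0.5, -1, 2)
  ex <- exact_shapley(f, x, bg)
  expect_lt(abs(sum(ex$phi) - (ex$fx - ex$baseline)), 1e-6)
  # two features with identical roles and identical values get equal phi
  g <- function(X) X[, 1] + X[, 2]
  bg2 <- cbind(a = rnorm(20), b = 0, c = rnorm(20))
  bg2[, 2] <- bg2[, 1]   # identical background columns
  exs <- exact_shapley(g, c(1.3, 1.3, 0.2), bg2)
  expect_equal(unname(exs$phi[1]), unname(exs$phi[2]), tolerance = 1e-10)
  expect_error(exact_shapley(g, c(1, 1, 1), matrix(0, 0, 3)), "nonempty")
})

test_that("Shapley on a trained classifier is fast and efficient", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20 * 7, -1), 20, 7), matrix(rnorm(20 * 7, 1), 20, 7))
  fit <- train_network(X, rep(0:1, each = 20), model_spec("cnn", epochs = 5, seed = 1))
  t0 <- Sys.time()
  ex <- exact_shapley(fit, X[1, ], X[seq(1, 40, by = 2), ])
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 1)
  expect_lt(ex$efficiency_gap, 1e-6)
})

test_that("LIME with no penalty recovers linear-model coefficients", {
  beta <- c(1.5, -2, 0.8)
  f <- function(X) drop(2 + X %*% beta)
  x <- c(0.3, -0.1, 1)
  lm0 <- lime_explain(f, x, n_perturb = 5000, lambda = 0, seed = 6)
  expect_lt(max(abs(lm0$coefficients - beta) / abs(beta)), 0.05)
  # and agrees with the closed-form weighted least-squares oracle
  d <- length(x)
  set.seed(6)  # replicate the generator's stream
  Z <- matrix(rnorm(5000 * d), 5000, d, byrow = TRUE) + matrix(x, 5000, d, byrow = TRUE)
  w <- exp(-rowSums(sweep(Z, 2, x)^2) / (0.75 * sqrt(d))^2)
  ref <- wls_fit(Z, f(Z), w)
  expect_equal(unname(lm0$coefficients), ref[-1], tolerance = 1e-6)
  expect_equal(lm0$intercept, ref[1], tolerance = 1e-6)
})

test_that("LIME is deterministic and collapses under a huge penalty", {
  f <- function(X) drop(X %*% c(1, 1))
  a <- lime_explain(f, c(0, 0), n_perturb = 200, seed = 9)
  b <- lime_explain(f, c(0, 0), n_perturb = 200, seed = 9)
  expect_identical(a$coefficients, b$coefficients)
  big <- lime_explain(f, c(0, 0), n_perturb = 200, lambda = 1e6, seed = 9)
  expect_equal(unname(big$coefficients), c(0, 0))
  expect_error(lime_explain(f, c(0, 0), n_perturb = 5), "at least")
})

test_that("LIME aggregation gives the population mean and spread per feature", {
  B <- rbind(c(1, 0), c(3, 0))
  ag <- aggregate_lime(B)
  expect_equal(ag$mean, c(2, 0))
  expect_equal(ag$sd, c(1, 0))
  # permutation over instances leaves the aggregate unchanged
  set.seed(2)
  M <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(aggregate_lime(M), aggregate_lime(M[sample(10), ]))
  expect_error(aggregate_lime(M[1, , drop = FALSE]), "at least 2")
})
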