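#' Exact Shapley attribution of one prediction
#'
#' Enumerates all `2^d` feature subsets (feasible for `d <= 15`) and computes
#' the exact Shapley value of each feature under marginal masking: the value
#' of a coalition `S` is the model's mean output over the background rows with
#' the features in `S` fixed to the explained instance's values.  Satisfies
#' efficiency (`sum(phi) = f(x) - baseline`) and symmetry by construction.
#'
#' @param model a fitted predictor: anything with a `predict(model, X)` method
#'   returning probabilities, or a plain function of a matrix.
#' @param x the instance to explain (numeric vector).
#' @param background reference rows (matrix, nonempty) defining the masking
#'   distribution.
#' @return object of class `"shapley_explanation"`: `phi` (named per-feature
#'   values), `baseline` (mean background prediction), `fx` (prediction at
#'   `x`), `efficiency_gap`.
#' @examples
#' f <- function(X) drop(X %*% c(2, -1, 0.5))
#' bg <- matrix(rnorm(30), 10, 3)
#' exact_shapley(f, c(1, 1, 1), bg)
#' @export
exact_shapley <- function(model, x, background) {
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("`background` must be nonempty", call. = FALSE)
  d <- length(x)
  if (d > 15L) stop("exact enumeration refused for more than 15 features", call. = FALSE)
  fwd <- if (is.function(model)) model else function(X) predict(model, X)
  B <- nrow(background)
  n_sub <- 2L^d
  # one big forward pass: subset s replaces masked features with x
  big <- matrix(0, n_sub * B, d)
  for (s in 0:(n_sub - 1L)) {
    blk <- background
    on <- which(bitwAnd(s, bitwShiftL(1L, 0:(d - 1L))) > 0L)
    if (length(on)) blk[, on] <- matrix(x[on], B, length(on), byrow = TRUE)
    big[(s * B + 1L):((s + 1L) * B), ] <- blk
  }
  colnames(big) <- names(x) %||% colnames(background)
  preds <- fwd(big)
  v <- vapply(0:(n_sub - 1L), function(s) mean(preds[(s * B + 1L):((s + 1L) * B)]),
              numeric(1))
  sizes <- vapply(0:(n_sub - 1L), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(d - 1L))) > 0L),
                  numeric(1))
  # weight |S|!(d-|S|-1)!/d! of each coalition S not containing j (the full
  # set never acts as such an S; give it weight 0)
  wt <- ifelse(sizes >= d, 0, factorial(sizes) * factorial(pmax(d - sizes - 1, 0)) / factorial(d))
  phi <- numeric(d)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_sub - 1L), bit) == 0L)  # 1-based positions = s+1
    s_wo <- without - 1L
    phi[j] <- sum(wt[without] * (v[s_wo + bit + 1L] - v[without]))
  }
  names(phi) <- names(x) %||% colnames(background) %||% paste0("f", seq_len(d))
  baseline <- v[1L]
  fx <- v[n_sub]
  structure(list(phi = phi, baseline = baseline, fx = fx,
                 efficiency_gap = abs(sum(phi) - (fx - baseline))),
            class = "shapley_explanation")
}

#' @export
print.shapley_explanation <- function(x, digits = 4, ...) {
  cat(sprintf("Exact Shapley attribution (baseline %.4f, f(x) %.4f, efficiency gap %.2e)\n",
              x$baseline, x$fx, x$efficiency_gap))
  print(round(x$phi, digits))
  invisible(x)
}

# coordinate-descent lasso for the locally weighted surrogate:
# minimises sum_i w_i (f_i - b0 - Z beta)^2 + lambda * sum |beta|
weighted_lasso <- function(Z, f, w, lambda, tol = 1e-9, max_iter = 1e4) {
  d <- ncol(Z)
  beta <- rep(0, d)
  b0 <- sum(w * f) / sum(w)
  wz2 <- colSums(w * Z^2)
  soft <- function(a, t) sign(a) * pmax(abs(a) - t, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    r <- f - b0 - drop(Z %*% beta)
    for (j in seq_len(d)) {
      r <- r + Z[, j] * beta[j]
      aj <- sum(w * Z[, j] * r)
      bj <- if (wz2[j] > 0) soft(aj, lambda / 2) / wz2[j] else 0
      delta <- max(delta, abs(bj - beta[j]))
      beta[j] <- bj
      r <- r - Z[, j] * beta[j]
    }
    b0_new <- b0 + sum(w * r) / sum(w)
    delta <- max(delta, abs(b0_new - b0))
    r <- r - (b0_new - b0)
    b0 <- b0_new
    if (delta < tol) break
  }
  list(beta = beta, intercept = b0, iterations = it)
}

#' Local surrogate (LIME) explanation of one prediction
#'
#' Draws Gaussian perturbations around the instance, weights them by an
#' exponential kernel on Euclidean distance, and fits an L1-regularised
#' weighted linear surrogate
#' `argmin_beta sum_i pi(z_i) (f(z_i) - b0 - z_i' beta)^2 + lambda ||beta||_1`.
#' Deterministic under the seed.
#'
#' @param model predictor as in [exact_shapley()].
#' @param x instance to explain.
#' @param n_perturb number of perturbations (must be `>= 10 * d`).
#' @param kernel_width kernel width; default `0.75 * sqrt(d)` (features are
#'   assumed standardised).
#' @param lambda L1 penalty (default 1e-3; `0` gives weighted least squares).
#' @param sigma perturbation standard deviation per feature.
#' @param seed integer seed.
#' @return object of class `"lime_explanation"`: `coefficients` (named beta),
#'   `intercept`, `kernel_width`, `lambda`, `seed`.
#' @export
lime_explain <- function(model, x, n_perturb = 5000,
                         kernel_width = 0.75 * sqrt(length(x)),
                         lambda = 1e-3, sigma = 1, seed = 1) {
  d <- length(x)
  if (n_perturb < 10 * d) stop("`n_perturb` must be at least 10 * d", call. = FALSE)
  fwd <- if (is.function(model)) model else function(X) predict(model, X)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_perturb * d, 0, sigma), n_perturb, d, byrow = TRUE) +
      matrix(x, n_perturb, d, byrow = TRUE)
    if (max(apply(Z, 2, function(z) diff(range(z)))) == 0) {
      stop("degenerate perturbations: all samples identical", call. = FALSE)
    }
    colnames(Z) <- names(x)
    f <- fwd(Z)
    w <- exp(-rowSums(sweep(Z, 2, x)^2) / kernel_width^2)
    fit <- weighted_lasso(Z, f, w, lambda)
    beta <- fit$beta
    names(beta) <- names(x) %||% paste0("f", seq_len(d))
    structure(list(coefficients = beta, intercept = fit$intercept,
                   kernel_width = kernel_width, lambda = lambda,
                   n_perturb = n_perturb, seed = seed),
              class = "lime_explanation")
  })
}

#' @export
print.lime_explanation <- function(x, digits = 4, ...) {
  cat(sprintf("LIME surrogate (kernel width %.3f, lambda %g, %d perturbations)\n",
              x$kernel_width, x$lambda, x$n_perturb))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Aggregate LIME explanations across instances
#'
#' Per-feature mean and population standard deviation of the per-instance
#' surrogate coefficients — the global importance summary.
#'
#' @param explanations a list of `"lime_explanation"` objects (>= 2), or a
#'   numeric matrix of coefficients (rows = instances).
#' @return data.frame (feature, mean, sd).
#' @export
aggregate_lime <- function(explanations) {
  B <- if (is.matrix(explanations)) explanations
       else do.call(rbind, lapply(explanations, function(e) e$coefficients))
  if (nrow(B) < 2L) stop("need at least 2 instances", call. = FALSE)
  data.frame(feature = colnames(B) %||% paste0("f", seq_len(ncol(B))),
             mean = colMeans(B),
             sd = apply(B, 2, sd_pop),
             stringsAsFactors = FALSE)
}
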