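#' Generating truth for one asymmetric lag-dependency pair
#'
#' Bundles the generating coefficients of a driver/response pair: intercept,
#' autoregressive coefficients, positive- and negative-branch distributed-lag
#' coefficients and the innovation scale.  The autoregressive part must be
#' stationary (`|sum(phi)| < 1`); non-stationary coefficient sets are rejected
#' with a diagnostic naming the offending sum.
#'
#' @param alpha intercept (default 0).
#' @param phi autoregressive coefficients, length p >= 1.
#' @param bpos,bneg branch coefficients, length p + 1 (lags 0..p).
#' @param sigma innovation standard deviation, > 0.
#' @return object of class `"nardl_truth"`.
#' @examples
#' nardl_truth(phi = c(0.3, 0.1), bpos = c(0.8, 0.3, 0), bneg = c(-0.5, 0, -0.2))
#' @export
nardl_truth <- function(alpha = 0, phi = c(0.3, 0.1),
                        bpos = c(0.8, 0.3, 0), bneg = c(-0.5, 0, -0.2),
                        sigma = 1) {
  p <- length(phi)
  if (p < 1L) stop("`phi` must have length >= 1", call. = FALSE)
  if (length(bpos) != p + 1L || length(bneg) != p + 1L) {
    stop("`bpos` and `bneg` must have length p + 1 = ", p + 1L, call. = FALSE)
  }
  if (abs(sum(phi)) >= 1) {
    stop(sprintf("non-stationary autoregression: |sum(phi)| = %.3f >= 1", abs(sum(phi))),
         call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(list(alpha = alpha, phi = as.numeric(phi), bpos = as.numeric(bpos),
                 bneg = as.numeric(bneg), sigma = sigma, p = p),
            class = "nardl_truth")
}

#' @export
print.nardl_truth <- function(x, ...) {
  cat(sprintf("Generating truth (p = %d): alpha = %g, sigma = %g\n", x$p, x$alpha, x$sigma))
  cat("  phi : ", paste(signif(x$phi, 4), collapse = ", "), "\n")
  cat("  b+  : ", paste(signif(x$bpos, 4), collapse = ", "), "\n")
  cat("  b-  : ", paste(signif(x$bneg, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one driver/response pair with known asymmetric lag dependence
#'
#' The driver is a stationary AR(1) (coefficient `x_ar`, default 0.5, so both
#' positive and negative increments occur); the response follows the
#' asymmetric distributed-lag recurrence with Gaussian innovations.  A burn-in
#' of `burn` steps is generated and discarded so the returned window does not
#' depend on start-up values.  Identical seeds give bit-identical output.
#'
#' @param truth a [nardl_truth()] object.
#' @param n number of retained time points; must exceed `10 * truth$p`.
#' @param seed integer seed.
#' @param burn burn-in steps discarded (default 200).
#' @param x_ar AR(1) coefficient of the driver.
#' @param x_sigma innovation scale of the driver.
#' @param mode partial-sum mode used in the generating recurrence.
#' @return list with `x`, `y` (length `n`), `eps` (the response innovations in
#'   the retained window) and the arguments used.
#' @examples
#' sim <- simulate_nardl_pair(nardl_truth(), n = 300, seed = 42)
#' @export
simulate_nardl_pair <- function(truth, n, seed, burn = 200, x_ar = 0.5,
                                x_sigma = 1, mode = c("increment", "cumulative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "nardl_truth"))
  n <- stop_if_not_scalar_count(n, "n", min = 2L)
  p <- truth$p
  if (n <= 10L * p) stop(sprintf("`n` must exceed 10 * p = %d", 10L * p), call. = FALSE)
  total <- n + burn
  with_seed(seed, {
    ex <- stats::rnorm(total, 0, x_sigma)
    x <- numeric(total)
    x[1] <- ex[1]
    for (t in 2:total) x[t] <- x_ar * x[t - 1L] + ex[t]
    ps <- decompose_partial_sums(x, mode = mode)
    eps <- stats::rnorm(total, 0, truth$sigma)
    y <- numeric(total)
    for (t in (p + 2L):total) {
      acc <- truth$alpha + eps[t]
      for (i in seq_len(p)) acc <- acc + truth$phi[i] * y[t - i]
      for (i in 0:p) {
        acc <- acc + truth$bpos[i + 1L] * ps$pos[t - i - 1L] +
          truth$bneg[i + 1L] * ps$neg[t - i - 1L]
      }
      y[t] <- acc
    }
    keep <- (burn + 1L):total
    list(x = x[keep], y = y[keep], eps = eps[keep], truth = truth,
         seed = seed, burn = burn, x_ar = x_ar, mode = mode)
  })
}

#' Cohort specification for the synthetic generator
#'
#' Describes a two-group cohort of multivariate ROI time series: group sizes,
#' number of ROIs, time points, and how the patient group's generating
#' couplings differ from controls.  The default group effect attenuates the
#' asymmetric branch coefficients and inflates the innovation noise of the
#' patient group, making patient networks more random; `"strong"` uses a
#' near-total attenuation intended to make the groups clearly separable, and
#' `"none"` generates exchangeable groups for null calibration.
#'
#' @param n_hc,n_pd subjects per group (>= 2 each).
#' @param n_rois number of ROIs (>= 3; default 48, the cortical parcellation
#'   size this generator emulates).
#' @param n_time time points per subject (> 10 * lag_order; default 210, a
#'   typical resting-state scan length).
#' @param lag_order generating lag order p.
#' @param group_effect `"attenuation"` (default), `"strong"` or `"none"`.
#' @param attenuation multiplier applied to the patient group's branch
#'   coefficients (ignored for `"none"`; `"strong"` forces 0.05).
#' @param noise_inflation multiplier on the patient innovation scale
#'   (`"strong"` keeps the default 1.25: the strong effect is near-total
#'   decoupling, not extra noise).
#' @param seed integer seed.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_hc = 20, n_pd = 60, n_rois = 48, n_time = 210,
                        lag_order = 2,
                        group_effect = c("attenuation", "strong", "none"),
                        attenuation = 0.5, noise_inflation = 1.25, seed = 1) {
  group_effect <- match.arg(group_effect)
  stop_if_not_scalar_count(n_hc, "n_hc", 2L)
  stop_if_not_scalar_count(n_pd, "n_pd", 2L)
  stop_if_not_scalar_count(n_rois, "n_rois", 3L)
  stop_if_not_scalar_count(lag_order, "lag_order", 1L)
  if (n_time <= 10L * lag_order) {
    stop("`n_time` must exceed 10 * lag_order", call. = FALSE)
  }
  if (group_effect == "strong") {
    attenuation <- 0.05
    noise_inflation <- 1.25
  }
  if (group_effect == "none") {
    attenuation <- 1
    noise_inflation <- 1
  }
  structure(list(n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
                 n_rois = as.integer(n_rois), n_time = as.integer(n_time),
                 lag_order = as.integer(lag_order), group_effect = group_effect,
                 attenuation = attenuation, noise_inflation = noise_inflation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d HC / %d PD, %d ROIs x %d time points, p = %d\n",
              x$n_hc, x$n_pd, x$n_rois, x$n_time, x$lag_order))
  cat(sprintf("  group effect: %s (attenuation %.2f, noise inflation %.2f), seed %d\n",
              x$group_effect, x$attenuation, x$noise_inflation, x$seed))
  invisible(x)
}

# generating truths per group: ROIs are paired (1 -> 2, 3 -> 4, ...); odd
# drivers are AR(1), even targets follow the asymmetric recurrence
cohort_truth <- function(spec) {
  base <- nardl_truth(alpha = 0, phi = c(0.3, 0.1)[seq_len(min(2, spec$lag_order))],
                      bpos = c(0.8, 0.3, rep(0, spec$lag_order - 1L)),
                      bneg = c(-0.5, 0, rep(-0.2, spec$lag_order - 1L)),
                      sigma = 1)
  if (spec$lag_order != 2L) {  # generic shapes for non-default p
    base <- nardl_truth(alpha = 0, phi = rep(0.3 / spec$lag_order, spec$lag_order),
                        bpos = c(0.8, rep(0.2, spec$lag_order)),
                        bneg = c(-0.5, rep(-0.1, spec$lag_order)),
                        sigma = 1)
  }
  pd <- nardl_truth(alpha = base$alpha, phi = base$phi,
                    bpos = base$bpos * spec$attenuation,
                    bneg = base$bneg * spec$attenuation,
                    sigma = base$sigma * spec$noise_inflation)
  pairs <- cbind(driver = seq(1L, spec$n_rois - 1L, by = 2L),
                 target = seq(2L, spec$n_rois, by = 2L))
  list(hc = base, pd = pd, pairs = pairs)
}

#' Simulate a two-group cohort of ROI time series
#'
#' Generates `n_hc + n_pd` subjects.  ROIs are organised as driver/target
#' pairs: odd-numbered ROIs are stationary AR(1) drivers and each even ROI
#' follows the asymmetric lag recurrence on its driver, with group-specific
#' coefficients from the spec's group effect.  Every subject gets an
#' independent, seed-derived realisation.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `"nardl_cohort"`: a list with `subjects` (each a
#'   list with `series` (n_time x n_rois matrix, ROI-name header),
#'   `subject_id`, `group`), `manifest` (data.frame subject_id, group),
#'   `truth` (generating coefficients per group and the coupled pair list) and
#'   `spec`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_hc = 3, n_pd = 3, n_rois = 6,
#'                                    n_time = 120, seed = 7))
#' dim(coh$subjects[[1]]$series)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- cohort_truth(spec)
  roi_names <- sprintf("ROI_%02d", seq_len(spec$n_rois))
  groups <- c(rep("HC", spec$n_hc), rep("PD", spec$n_pd))
  ids <- sprintf("sub-%03d", seq_along(groups))
  subjects <- vector("list", length(groups))
  derive_seed <- function(s, pr) {
    as.integer((as.numeric(spec$seed) * 100003 + s * 1009 + pr) %% 2147483647)
  }
  for (s in seq_along(groups)) {
    g_truth <- if (groups[s] == "HC") truth$hc else truth$pd
    mat <- matrix(NA_real_, spec$n_time, spec$n_rois,
                  dimnames = list(NULL, roi_names))
    for (pr in seq_len(nrow(truth$pairs))) {
      sim <- simulate_nardl_pair(g_truth, n = spec$n_time,
                                 seed = derive_seed(s, pr))
      mat[, truth$pairs[pr, "driver"]] <- sim$x
      mat[, truth$pairs[pr, "target"]] <- sim$y
    }
    if (spec$n_rois %% 2L == 1L) {  # leftover ROI: plain AR(1)
      mat[, spec$n_rois] <- with_seed(derive_seed(s, 0L), {
        e <- stats::rnorm(spec$n_time + 200L)
        z <- numeric(length(e))
        z[1] <- e[1]
        for (t in 2:length(e)) z[t] <- 0.5 * z[t - 1L] + e[t]
        z[(length(e) - spec$n_time + 1L):length(e)]
      })
    }
    subjects[[s]] <- list(series = mat, subject_id = ids[s], group = groups[s])
  }
  structure(list(subjects = subjects,
                 manifest = data.frame(subject_id = ids, group = groups,
                                       stringsAsFactors = FALSE),
                 truth = truth, spec = spec),
            class = "nardl_cohort")
}

#' @export
print.nardl_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d HC / %d PD), %d ROIs x %d time points\n",
              length(x$subjects), x$spec$n_hc, x$spec$n_pd, x$spec$n_rois, x$spec$n_time))
  cat(sprintf("  group effect: %s, seed %d\n", x$spec$group_effect, x$spec$seed))
  invisible(x)
}

#' Small weighted fixture networks
#'
#' Deterministic (or seeded) symmetric weighted adjacency matrices used as
#' oracle inputs for the graph-metric and information-theory stages.
#'
#' @param kind one of `"uniform"` (complete, all weights 1), `"star"` (node 1
#'   is the hub), `"ring"` (cycle), `"two_cliques"` (two dense blocks joined
#'   by one weak bridge) or `"random"` (i.i.d. uniform weights).
#' @param n number of nodes (>= 2).
#' @param seed integer seed (used by `"random"` only).
#' @return n x n symmetric matrix, zero diagonal, weights in `[0, 1]`.
#' @examples
#' make_fixture_network("star", 4)
#' @export
make_fixture_network <- function(kind = c("uniform", "star", "ring", "two_cliques", "random"),
                                 n, seed = 1) {
  kind <- match.arg(kind)
  n <- stop_if_not_scalar_count(n, "n", 2L)
  W <- matrix(0, n, n)
  if (kind == "uniform") {
    W[] <- 1
    diag(W) <- 0
  } else if (kind == "star") {
    W[1, 2:n] <- 1
    W[2:n, 1] <- 1
  } else if (kind == "ring") {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      W[i, j] <- W[j, i] <- 1
    }
  } else if (kind == "two_cliques") {
    h <- ceiling(n / 2)
    W[seq_len(h), seq_len(h)] <- 0.9
    W[(h + 1):n, (h + 1):n] <- 0.8
    diag(W) <- 0
    W[h, h + 1L] <- W[h + 1L, h] <- 0.1
  } else {
    W <- with_seed(seed, {
      M <- matrix(0, n, n)
      up <- upper.tri(M)
      M[up] <- stats::runif(sum(up))
      M + t(M)
    })
  }
  dimnames(W) <- list(sprintf("n%02d", seq_len(n)), sprintf("n%02d", seq_len(n)))
  W
}

#' Write a synthetic cohort to delimited text files
#'
#' One CSV per subject (n_time rows x n_rois columns with an ROI-name header),
#' a `manifest.csv` (subject_id, group, path) and, when the jsonlite package
#' is available, a `truth.json` sidecar with the generating coefficients.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame with file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nardl_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort$subjects, function(s) {
    path <- file.path(dir, paste0(s$subject_id, ".csv"))
    utils::write.csv(as.data.frame(s$series), path, row.names = FALSE)
    path
  }, character(1))
  manifest <- cbind(cohort$manifest, path = paths, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- cohort$truth
    jsonlite::write_json(
      list(hc = unclass(truth$hc), pd = unclass(truth$pd),
           pairs = as.data.frame(truth$pairs)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()] (or any external extraction
#' following the same layout) back into a cohort object
#'
#' @param dir directory containing `manifest.csv` and per-subject CSVs.
#' @return object of class `"nardl_cohort"` (without generating truth).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    mat <- as.matrix(utils::read.csv(manifest$path[i], check.names = FALSE))
    list(series = mat, subject_id = manifest$subject_id[i], group = manifest$group[i])
  })
  structure(list(subjects = subjects,
                 manifest = manifest[, c("subject_id", "group")],
                 truth = NULL, spec = NULL),
            class = "nardl_cohort")
}
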