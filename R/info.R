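# Information-theoretic network descriptors: cell-probability matrix, network
# Shannon entropy, thresholded binarisation, integrated-information Phi by
# bipartition sampling (with an exhaustive oracle for small graphs),
# disequilibrium and statistical complexity.
#
# Conventions: natural logarithms throughout.  The network entropy (the
# feature) uses the ordered-cell double sum over the probability matrix; the
# Phi informations count unordered edges of the binarised graph, under which a
# single-edge graph carries zero information and Phi vanishes identically.

#' Edge-probability matrix of a weighted network
#'
#' Divides each cell of the (symmetric, nonnegative) weight matrix by the
#' total over all cells, giving a probability distribution over ordered node
#' pairs (diagonal zero).
#'
#' @param W weighted adjacency matrix or network object.
#' @return matrix `p` with `sum(p) == 1` (within 1e-12).
#' @export
edge_probability_distribution <- function(W) {
  W <- as_adjacency(W)
  check_symmetric_nonneg(W)
  if (any(W < 0)) stop("weights must be nonnegative", call. = FALSE)
  tot <- sum(W)
  if (tot == 0) stop("all-zero weight matrix has no probability distribution", call. = FALSE)
  W / tot
}

#' Network Shannon entropy
#'
#' `-sum(p * log(p))` over the positive cells of the edge-probability matrix
#' (ordered double sum, natural log).
#'
#' @param p an [edge_probability_distribution()] matrix.
#' @return scalar entropy in nats.
#' @export
network_entropy <- function(p) {
  pp <- p[p > 0]
  -sum(pp * log(pp))
}

#' Binarise an edge-probability matrix
#'
#' Keeps every cell whose probability is at least `theta` times the maximum
#' cell probability; the diagonal is forced to zero.
#'
#' @param p probability matrix.
#' @param theta threshold fraction in (0, 1]; default 0.001.
#' @return binary 0/1 matrix.
#' @export
binarize_probability <- function(p, theta = 0.001) {
  if (!is.numeric(theta) || theta <= 0 || theta > 1) {
    stop("`theta` must lie in (0, 1]", call. = FALSE)
  }
  b <- (p >= theta * max(p)) * 1
  diag(b) <- 0
  b
}

# unordered edge count within a node subset
edges_within <- function(b, S) sum(b[S, S, drop = FALSE]) / 2

#' Information content of a subsystem
#'
#' Shannon entropy of the binarised connection distribution restricted to the
#' node subset `S` and renormalised to sum one.  On a binary graph this is the
#' log of the number of within-subset edges; a subset with no internal edges
#' carries zero information.
#'
#' @param b binary symmetric adjacency matrix.
#' @param S integer vector of node indices (nonempty).
#' @return scalar information in nats.
#' @export
subsystem_information <- function(b, S) {
  if (!length(S)) stop("`S` must be nonempty", call. = FALSE)
  m <- edges_within(b, S)
  if (m <= 0) return(0)
  log(m)
}

#' Integrated information by bipartition sampling
#'
#' Estimates Phi as the average over `n_samples` random bipartitions of
#' whole-network information minus the summed information of the two parts:
#' for each draw a subset size `k` is sampled uniformly from `1..n-1`, then a
#' uniform random `k`-subset `S`, and
#' `Phi_partition = I(G) - (I(G_S) + I(G_S'))`.  Note this sampling measure is
#' size-stratified, not uniform over bipartitions; the exhaustive oracle
#' [exhaustive_phi()] weights bipartitions identically.
#'
#' @param b binary symmetric adjacency matrix (from [binarize_probability()]).
#' @param n_samples number of sampled bipartitions (default 10000).
#' @param seed integer seed; identical seeds give identical estimates.
#' @param theta recorded threshold (metadata only).
#' @return object of class `"phi_estimate"`: `phi`, `se` (per-sample standard
#'   error), `n_samples`, `mode = "sampled"`, `seed`, `theta`.
#' @export
estimate_phi <- function(b, n_samples = 10000, seed = 1, theta = NA_real_) {
  n <- nrow(b)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  n_samples <- stop_if_not_scalar_count(n_samples, "n_samples", 1L)
  m_total <- sum(b) / 2
  i_g <- if (m_total > 0) log(m_total) else 0
  with_seed(seed, {
    k <- sample.int(n - 1L, n_samples, replace = TRUE)
    M <- matrix(FALSE, n_samples, n)
    for (r in seq_len(n_samples)) M[r, sample.int(n, k[r])] <- TRUE
    # within-subset ordered cell counts via (M b) o M, halved for unordered
    mS <- rowSums((M %*% b) * M) / 2
    Mc <- !M
    mSc <- rowSums((Mc %*% b) * Mc) / 2
    iS <- ifelse(mS > 0, log(mS), 0)
    iSc <- ifelse(mSc > 0, log(mSc), 0)
    phi_part <- i_g - (iS + iSc)
    structure(list(phi = mean(phi_part),
                   se = stats::sd(phi_part) / sqrt(n_samples),
                   n_samples = n_samples, mode = "sampled", seed = seed,
                   theta = theta),
              class = "phi_estimate")
  })
}

#' Exact integrated information over all bipartitions
#'
#' Enumerates every nontrivial bipartition of up to 14 nodes and returns the
#' weighted mean of `Phi_partition`, with each bipartition weighted exactly as
#' the size-stratified sampler of [estimate_phi()] would draw it (subset size
#' uniform on `1..n-1`, subset uniform given size), so the sampler is unbiased
#' for this value.  Serves as the oracle for the sampled estimator.
#'
#' @param b binary symmetric adjacency matrix, `n <= 14`.
#' @param weighting `"size_stratified"` (default, matches the sampler) or
#'   `"uniform"` (every unordered bipartition equally weighted).
#' @return object of class `"phi_estimate"` with `mode = "exhaustive"`.
#' @export
exhaustive_phi <- function(b, weighting = c("size_stratified", "uniform")) {
  weighting <- match.arg(weighting)
  n <- nrow(b)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (n > 14L) stop("exhaustive enumeration refused for n > 14", call. = FALSE)
  m_total <- sum(b) / 2
  i_g <- if (m_total > 0) log(m_total) else 0
  subsets <- seq_len(2L^n - 2L)   # all nonempty proper subsets, as bitmasks
  M <- matrix(FALSE, length(subsets), n)
  for (j in seq_len(n)) M[, j] <- bitwAnd(subsets, bitwShiftL(1L, j - 1L)) > 0L
  k <- rowSums(M)
  mS <- rowSums((M %*% b) * M) / 2
  Mc <- !M
  mSc <- rowSums((Mc %*% b) * Mc) / 2
  phi_part <- i_g - (ifelse(mS > 0, log(mS), 0) + ifelse(mSc > 0, log(mSc), 0))
  w <- if (weighting == "size_stratified") {
    1 / ((n - 1) * choose(n, k))
  } else {
    rep(1 / length(subsets), length(subsets))
  }
  structure(list(phi = sum(w * phi_part), se = NA_real_,
                 n_samples = length(subsets) / 2L, mode = "exhaustive",
                 seed = NA_integer_, theta = NA_real_),
            class = "phi_estimate")
}

#' @export
print.phi_estimate <- function(x, ...) {
  if (x$mode == "sampled") {
    cat(sprintf("Phi = %.6f (se %.6f) from %d sampled bipartitions [seed %d]\n",
                x$phi, x$se, x$n_samples, x$seed))
  } else {
    cat(sprintf("Phi = %.6f (exhaustive over %d unordered bipartitions)\n",
                x$phi, x$n_samples))
  }
  invisible(x)
}

#' Disequilibrium of an edge-probability matrix
#'
#' Euclidean distance between the cell-probability distribution and the
#' uniform distribution `1/n^2` over all `n^2` ordered cells (the zero
#' diagonal included).
#'
#' @param p probability matrix.
#' @return scalar `D >= 0`.
#' @export
disequilibrium <- function(p) {
  n <- nrow(p)
  sqrt(sum((p - 1 / n^2)^2))
}

#' Statistical complexity
#'
#' The product `C = H * D` of network entropy and disequilibrium; the vertical
#' coordinate of the complexity-entropy plane.
#'
#' @param H entropy in nats.
#' @param D disequilibrium.
#' @return scalar complexity.
#' @export
statistical_complexity <- function(H, D) H * D

#' Complexity-entropy plane coordinates
#'
#' Convenience constructor for one subject's point on the H-C plane.
#'
#' @param H entropy; @param C complexity; @param group optional group label;
#' @param subject_id optional id.
#' @return one-row data.frame (subject_id, group, H, C).
#' @export
hc_coordinates <- function(H, C, group = NA_character_, subject_id = NA_character_) {
  data.frame(subject_id = subject_id, group = group, H = H, C = C,
             stringsAsFactors = FALSE)
}
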