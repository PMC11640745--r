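#' Full feature vector for one subject
#'
#' Runs the whole per-subject pipeline: pairwise asymmetric-lag dependency
#' network, min-max normalisation, PMFG filtration, weighted centralities,
#' and the information-theoretic block (network entropy, disequilibrium,
#' statistical complexity, sampled integrated information Phi).  By default
#' all graph measures are computed on the PMFG-filtered network; set
#' `source = "full"` to use the dense normalised matrix instead.
#'
#' @param ts n_time x n_rois matrix (or cohort subject entry).
#' @param p lag order.
#' @param symmetrization,mode,cd_form passed to [build_dependency_matrix()].
#' @param source `"pmfg"` (default) or `"full"`.
#' @param theta binarisation threshold fraction for Phi.
#' @param phi_samples sampled bipartitions for Phi.
#' @param seed seed for the Phi sampler.
#' @return named numeric vector with elements `mean_degree`, `mean_closeness`,
#'   `mean_betweenness`, `mean_eigenvector`, `network_entropy`, `complexity`,
#'   `phi`, plus auxiliaries `phi_se` and `disequilibrium`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_hc = 2, n_pd = 2, n_rois = 6,
#'                                    n_time = 150, seed = 2))
#' subject_features(coh$subjects[[1]], phi_samples = 200, seed = 1)
#' @export
subject_features <- function(ts, p = 2, symmetrization = "mean",
                             mode = "increment", cd_form = "text",
                             source = c("pmfg", "full"), theta = 0.001,
                             phi_samples = 10000, seed = 1) {
  source <- match.arg(source)
  net <- build_dependency_matrix(ts, p = p, symmetrization = symmetrization,
                                 mode = mode, cd_form = cd_form)
  net <- normalize_minmax(net)
  W <- if (source == "pmfg") as.matrix(pmfg(net, verify = FALSE)) else as.matrix(net)
  nm <- node_metrics(W, source = source)
  means <- node_metric_means(nm)
  pmat <- edge_probability_distribution(W)
  H <- network_entropy(pmat)
  D <- disequilibrium(pmat)
  C <- statistical_complexity(H, D)
  b <- binarize_probability(pmat, theta = theta)
  phi <- estimate_phi(b, n_samples = phi_samples, seed = seed, theta = theta)
  c(means, network_entropy = H, complexity = C, phi = phi$phi,
    phi_se = phi$se, disequilibrium = D)
}

#' Feature table for a whole cohort
#'
#' Applies [subject_features()] to every subject and assembles the cohort
#' feature table used by the statistical battery and the classifiers.  Each
#' subject's Phi sampler gets a seed derived deterministically from `seed` and
#' the subject index, so the table is reproducible as a whole.
#'
#' @param cohort a `"nardl_cohort"` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param ... passed to [subject_features()].
#' @param seed base seed for the Phi samplers.
#' @return data.frame: subject_id, group, the 7 features, phi_se,
#'   disequilibrium.  The 7 feature columns are `mean_degree`,
#'   `mean_closeness`, `mean_betweenness`, `mean_eigenvector`,
#'   `network_entropy`, `complexity`, `phi`.
#' @export
cohort_features <- function(cohort, ..., seed = 1) {
  stopifnot(inherits(cohort, "nardl_cohort"))
  rows <- lapply(seq_along(cohort$subjects), function(s) {
    sub <- cohort$subjects[[s]]
    fv <- subject_features(sub$series, ..., seed = (seed * 7919 + s) %% 2147483647)
    cbind(data.frame(subject_id = sub$subject_id, group = sub$group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Names of the 7 subject-level features
#' @return character vector in canonical order.
#' @export
feature_names <- function() {
  c("mean_degree", "mean_closeness", "mean_betweenness", "mean_eigenvector",
    "network_entropy", "complexity", "phi")
}
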