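#' Construct a dependency network from a raw weight matrix
#'
#' Container used throughout the pipeline: raw symmetric weight matrix `W`,
#' optional min-max normalised matrix `W_norm`, ROI names and a per-edge QC
#' table.
#'
#' @param W square symmetric numeric matrix with zero diagonal.
#' @param roi_names optional character vector (defaults to `colnames(W)`).
#' @param symmetrization tag recording how ordered scores were combined.
#' @param qc optional per-ordered-fit QC data.frame.
#' @return object of class `"dependency_network"`.
#' @export
dependency_network <- function(W, roi_names = colnames(W),
                               symmetrization = "mean", qc = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("`W` must be square", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10) stop("`W` must be symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("`W` must have a zero diagonal", call. = FALSE)
  if (is.null(roi_names)) roi_names <- sprintf("ROI_%02d", seq_len(nrow(W)))
  dimnames(W) <- list(roi_names, roi_names)
  structure(list(roi_names = roi_names, W = W, W_norm = NULL,
                 symmetrization = symmetrization, qc = qc),
            class = "dependency_network")
}

#' Pairwise combined-dependency adjacency matrix
#'
#' Fits the asymmetric distributed-lag model in both ordered directions for
#' every unordered ROI pair and combines the two directed combined-dependency
#' scores into a symmetric raw weight matrix (diagonal zero).  Degenerate or
#' long-run-flagged fits are recorded per ordered direction in the QC table.
#'
#' @param ts an n_time x n_rois numeric matrix with ROI-name column header, or
#'   a cohort subject entry (list with a `series` matrix).
#' @param p lag order (default 2).
#' @param symmetrization `"mean"` (default) or `"max"` of the two directed
#'   scores.
#' @param mode,cd_form,denom_floor,longrun_cap passed to [nardl()].
#' @return a `"dependency_network"` with raw `W` filled (run
#'   [normalize_minmax()] to fill `W_norm`).
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_hc = 2, n_pd = 2, n_rois = 4,
#'                                    n_time = 150, seed = 1))
#' net <- build_dependency_matrix(coh$subjects[[1]]$series)
#' @export
build_dependency_matrix <- function(ts, p = 2,
                                    symmetrization = c("mean", "max"),
                                    mode = "increment", cd_form = "text",
                                    denom_floor = 1e-3, longrun_cap = 1e3) {
  symmetrization <- match.arg(symmetrization)
  if (is.list(ts) && !is.null(ts$series)) ts <- ts$series
  ts <- as.matrix(ts)
  n <- ncol(ts)
  if (n < 3L) stop("need at least 3 ROIs", call. = FALSE)
  roi <- colnames(ts) %||% sprintf("ROI_%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(roi, roi))
  qc <- vector("list", n * (n - 1L))
  q <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      f_ij <- nardl(ts[, j], ts[, i], p = p, mode = mode, cd_form = cd_form,
                    denom_floor = denom_floor, longrun_cap = longrun_cap)
      f_ji <- nardl(ts[, i], ts[, j], p = p, mode = mode, cd_form = cd_form,
                    denom_floor = denom_floor, longrun_cap = longrun_cap)
      cds <- c(f_ij$cd, f_ji$cd)
      W[i, j] <- W[j, i] <- if (symmetrization == "mean") mean(cds) else max(cds)
      qc[[q + 1L]] <- data.frame(from = roi[i], to = roi[j], cd = f_ij$cd,
                                 degenerate = f_ij$degenerate,
                                 longrun_flagged = f_ij$longrun_flagged)
      qc[[q + 2L]] <- data.frame(from = roi[j], to = roi[i], cd = f_ji$cd,
                                 degenerate = f_ji$degenerate,
                                 longrun_flagged = f_ji$longrun_flagged)
      q <- q + 2L
    }
  }
  dependency_network(W, roi, symmetrization = symmetrization,
                     qc = do.call(rbind, qc))
}

#' Min-max normalise a dependency network
#'
#' Rescales the off-diagonal raw weights to `[0, 1]`:
#' `W'_ij = (W_ij - min W) / (max W - min W)` over off-diagonal entries, so
#' even negative raw dependencies map into the unit interval.  The diagonal
#' stays zero.  A constant matrix cannot be scaled: all off-diagonal entries
#' are set to 0 with a warning.
#'
#' @param net a `"dependency_network"` (raw `W` present) or a plain symmetric
#'   matrix.
#' @return the network with `W_norm` filled (a `"dependency_network"`).
#' @export
normalize_minmax <- function(net) {
  if (!inherits(net, "dependency_network")) net <- dependency_network(net)
  W <- net$W
  off <- W[upper.tri(W) | lower.tri(W)]
  lo <- min(off)
  hi <- max(off)
  Wn <- W
  if (hi == lo) {
    warning("constant weight matrix: all normalised weights set to 0")
    Wn[upper.tri(Wn) | lower.tri(Wn)] <- 0
  } else {
    Wn[] <- (W - lo) / (hi - lo)
  }
  diag(Wn) <- 0
  net$W_norm <- Wn
  net
}

#' @export
as.matrix.dependency_network <- function(x, which = c("norm", "raw"), ...) {
  which <- match.arg(which)
  if (which == "raw") return(x$W)
  if (is.null(x$W_norm)) stop("network not normalised yet; run normalize_minmax()", call. = FALSE)
  x$W_norm
}

#' @export
print.dependency_network <- function(x, ...) {
  n <- length(x$roi_names)
  cat(sprintf("Dependency network: %d ROIs, symmetrization = %s, %s\n",
              n, x$symmetrization,
              if (is.null(x$W_norm)) "raw weights only" else "normalised"))
  off <- x$W[upper.tri(x$W)]
  cat(sprintf("  raw weights: min %.4f / median %.4f / max %.4f\n",
              min(off), stats::median(off), max(off)))
  if (!is.null(x$qc) && any(x$qc$degenerate | x$qc$longrun_flagged)) {
    cat(sprintf("  flagged ordered fits: %d of %d\n",
                sum(x$qc$degenerate | x$qc$longrun_flagged), nrow(x$qc)))
  }
  invisible(x)
}

#' Export a weighted network to GraphML
#'
#' Writes the normalised dependency network (or a PMFG backbone / plain
#' weighted adjacency) as an undirected weighted GraphML file.
#'
#' @param net a `"dependency_network"` (normalised), `"pmfg"` or weighted
#'   adjacency matrix.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  W <- as_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network's edges as a long table
#'
#' @param net a `"dependency_network"` (normalised or not).
#' @return data.frame with columns roi_i, roi_j, weight, weight_norm, qc_flag.
#' @export
edge_table <- function(net) {
  stopifnot(inherits(net, "dependency_network"))
  n <- length(net$roi_names)
  idx <- which(upper.tri(net$W), arr.ind = TRUE)
  flag <- rep(FALSE, nrow(idx))
  if (!is.null(net$qc)) {
    bad <- net$qc[net$qc$degenerate | net$qc$longrun_flagged, , drop = FALSE]
    if (nrow(bad)) {
      key_bad <- unique(c(paste(bad$from, bad$to), paste(bad$to, bad$from)))
      key <- paste(net$roi_names[idx[, 1]], net$roi_names[idx[, 2]])
      flag <- key %in% key_bad
    }
  }
  data.frame(roi_i = net$roi_names[idx[, 1]], roi_j = net$roi_names[idx[, 2]],
             weight = net$W[idx],
             weight_norm = if (is.null(net$W_norm)) NA_real_ else net$W_norm[idx],
             qc_flag = flag, stringsAsFactors = FALSE)
}
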