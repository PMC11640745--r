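# Weighted graph metrics.  Edge weights are connection strengths; path costs
# are reciprocal weights (1/w), so strong edges are short.  Shortest-path
# machinery (Dijkstra distances, betweenness with path multiplicities) is
# delegated to igraph; eigenvector centrality is computed here by power
# iteration with a dense eigendecomposition fallback.

metric_graph <- function(W) {
  check_symmetric_nonneg(W)
  if (any(W < 0)) stop("edge weights must be nonnegative", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  list(g = g, cost = 1 / igraph::E(g)$weight)
}

#' Weighted degree (strength) centrality
#'
#' Row sums of the weighted adjacency: the total connection strength incident
#' to each node.
#'
#' @param net weighted adjacency matrix (or `"pmfg"` / `"dependency_network"`
#'   object).
#' @return named numeric vector, one value per node.
#' @export
weighted_degree <- function(net) {
  W <- as_adjacency(net)
  check_symmetric_nonneg(W)
  rowSums(W)
}

#' All-pairs weighted shortest-path distances
#'
#' Path cost is the sum of reciprocal edge weights along the path
#' (strong edges are cheap to traverse); the distance is the minimum cost over
#' paths.  Disconnected pairs get `Inf` and the result carries a
#' `disconnected` attribute flag.
#'
#' @param net weighted adjacency matrix or network object.
#' @return symmetric distance matrix with zero diagonal.
#' @export
weighted_shortest_paths <- function(net) {
  W <- as_adjacency(net)
  mg <- metric_graph(W)
  D <- igraph::distances(mg$g, weights = mg$cost)
  dimnames(D) <- dimnames(W)
  attr(D, "disconnected") <- any(is.infinite(D))
  D
}

#' Weighted closeness centrality
#'
#' Reciprocal of the summed shortest-path distances from a node to all
#' others.  On a disconnected graph the sum runs over the node's own connected
#' component (infinite distances would make closeness identically zero) and
#' the result carries a `disconnected` attribute flag.
#'
#' @param net weighted adjacency matrix or network object.
#' @return named numeric vector.
#' @export
closeness_w <- function(net) {
  D <- weighted_shortest_paths(net)
  n <- nrow(D)
  out <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d) || sum(d) == 0) return(0)
    1 / sum(d)
  }, numeric(1))
  names(out) <- rownames(D)
  attr(out, "disconnected") <- attr(D, "disconnected")
  out
}

#' Weighted betweenness centrality
#'
#' For each node, the sum over unordered pairs of other nodes of the fraction
#' of shortest paths (under reciprocal-weight costs) passing through it;
#' unnormalised.  On disconnected graphs only connected pairs contribute.
#'
#' @param net weighted adjacency matrix or network object.
#' @return named numeric vector.
#' @export
betweenness_w <- function(net) {
  W <- as_adjacency(net)
  mg <- metric_graph(W)
  out <- igraph::betweenness(mg$g, weights = mg$cost, directed = FALSE)
  names(out) <- rownames(W)
  out
}

#' Weighted eigenvector centrality
#'
#' Principal eigenvector of the weighted adjacency matrix, computed by power
#' iteration (tolerance 1e-10, at most 1e4 iterations) with a dense
#' eigendecomposition fallback on non-convergence.  The returned vector is
#' nonnegative with unit Euclidean norm; on a disconnected graph it
#' concentrates on the spectrally dominant component.
#'
#' @param net weighted adjacency matrix or network object.
#' @param tol convergence tolerance on the iterate change.
#' @param max_iter maximum power iterations.
#' @return named numeric vector with attribute `lambda` (the dominant
#'   eigenvalue).
#' @export
eigenvector_w <- function(net, tol = 1e-10, max_iter = 1e4) {
  W <- as_adjacency(net)
  check_symmetric_nonneg(W)
  n <- nrow(W)
  if (all(W == 0)) {
    out <- rep(0, n)
    names(out) <- rownames(W)
    attr(out, "lambda") <- 0
    return(out)
  }
  v <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- drop(W %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    if (sqrt(sum((u - v)^2)) < tol) {
      v <- u
      converged <- TRUE
      break
    }
    v <- u
  }
  if (!converged) {
    es <- eigen(W, symmetric = TRUE)
    v <- es$vectors[, which.max(es$values)]
  }
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  lambda <- drop(crossprod(v, W %*% v))
  names(v) <- rownames(W)
  attr(v, "lambda") <- lambda
  v
}

#' Edge-weight entropy of a weighted graph
#'
#' Shannon entropy (natural log) of the normalised edge-weight distribution:
#' each edge's weight divided by the total weight is treated as a probability.
#' Maximal (`log m` for `m` edges) when all weights are equal.
#'
#' @param net weighted adjacency matrix or network object.
#' @return scalar entropy in nats.
#' @export
edge_weight_entropy <- function(net) {
  W <- as_adjacency(net)
  check_symmetric_nonneg(W)
  w <- W[upper.tri(W)]
  w <- w[w > 0]
  if (!length(w)) stop("empty graph: no positive-weight edges", call. = FALSE)
  p <- w / sum(w)
  -sum(p * log(p))
}

#' Per-node centrality table for one network
#'
#' Computes the four weighted centralities for every node plus the graph-level
#' edge-weight entropy.
#'
#' @param net weighted adjacency matrix or network object.
#' @param source tag recording which graph the metrics were computed on
#'   (`"pmfg"` or `"full"`).
#' @return data.frame (node, degree, closeness, betweenness, eigenvector) with
#'   attributes `edge_entropy`, `source` and `disconnected`.
#' @export
node_metrics <- function(net, source = c("pmfg", "full")) {
  source <- match.arg(source)
  W <- as_adjacency(net)
  deg <- weighted_degree(W)
  clo <- closeness_w(W)
  bet <- betweenness_w(W)
  eig <- eigenvector_w(W)
  out <- data.frame(node = rownames(W) %||% as.character(seq_len(nrow(W))),
                    degree = as.numeric(deg), closeness = as.numeric(clo),
                    betweenness = as.numeric(bet), eigenvector = as.numeric(eig),
                    stringsAsFactors = FALSE)
  attr(out, "edge_entropy") <- edge_weight_entropy(W)
  attr(out, "source") <- source
  attr(out, "disconnected") <- isTRUE(attr(clo, "disconnected"))
  out
}

#' Node-mean centralities
#'
#' Arithmetic means over nodes of the four centralities in a [node_metrics()]
#' table — the centrality block of the subject feature vector.
#'
#' @param metrics a [node_metrics()] data.frame.
#' @return named numeric vector (mean_degree, mean_closeness,
#'   mean_betweenness, mean_eigenvector).
#' @export
node_metric_means <- function(metrics) {
  c(mean_degree = mean(metrics$degree),
    mean_closeness = mean(metrics$closeness),
    mean_betweenness = mean(metrics$betweenness),
    mean_eigenvector = mean(metrics$eigenvector))
}
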