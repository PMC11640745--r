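# Independent brute-force oracles used against the package implementations.

# all-pairs shortest paths under reciprocal-weight costs, Floyd-Warshall
brute_shortest_paths <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# enumerate every simple path between two nodes with its cost
all_simple_paths_cost <- function(W, s, t) {
  n <- nrow(W)
  out <- list()
  rec <- function(path, cost) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- list(path = path, cost = cost)
      return()
    }
    for (w in seq_len(n)) {
      if (W[v, w] > 0 && !(w %in% path)) rec(c(path, w), cost + 1 / W[v, w])
    }
  }
  rec(s, 0)
  out
}

# unnormalised weighted betweenness by exhaustive shortest-path enumeration
brute_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_simple_paths_cost(W, s, t)
      if (!length(paths)) next
      costs <- vapply(paths, `[[`, numeric(1), "cost")
      best <- min(costs)
      sp <- paths[costs <= best + tol]
      sigma <- length(sp)
      through <- numeric(n)
      for (p in sp) {
        inner <- setdiff(p$path, c(s, t))
        through[inner] <- through[inner] + 1
      }
      bc <- bc + through / sigma
    }
  }
  bc
}

# Mann-Whitney U by direct pairwise comparison (ties count half)
brute_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# batch planarity oracle: networkx's LR planarity test through python.
# graphs: list of 2-column edge matrices.  Returns logical vector.
networkx_planarity <- function(graphs) {
  inp <- tempfile(fileext = ".txt")
  out <- tempfile(fileext = ".txt")
  lines <- vapply(graphs, function(el) {
    paste(apply(el, 1, paste, collapse = ","), collapse = ";")
  }, character(1))
  writeLines(lines, inp)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, networkx as nx",
    "res = []",
    "for line in open(sys.argv[1]):",
    "    line = line.strip()",
    "    g = nx.Graph()",
    "    for tok in line.split(';'):",
    "        a, b = tok.split(',')",
    "        g.add_edge(int(a), int(b))",
    "    res.append('1' if nx.check_planarity(g)[0] else '0')",
    "open(sys.argv[2], 'w').write('\\n'.join(res) + '\\n')"
  ), script)
  status <- system2("python", c(script, inp, out))
  stopifnot(status == 0)
  readLines(out) == "1"
}

# numerical gradient of the (unclamped) binary cross-entropy
numeric_nn_grad <- function(spec, params, X, y, eps = 1e-6) {
  loss <- function(p) {
    pr <- nardlnet:::nn_forward(spec, p, X)$prob
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  g <- params
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      g[[nm]][i] <- (loss(p1) - loss(p2)) / (2 * eps)
    }
  }
  g
}

# weighted least squares with intercept (LIME oracle at lambda = 0)
wls_fit <- function(Z, f, w) {
  Z1 <- cbind(1, Z)
  A <- crossprod(Z1 * w, Z1)
  drop(solve(A, crossprod(Z1 * w, f)))
}
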