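# Planarity testing via Demoucron's incremental face-embedding algorithm,
# run per biconnected component (a graph is planar iff every biconnected
# component is).  Faces are kept as boundary cycles; embedding a fragment
# path through an admissible face splits it in two.  Nonplanarity certificates
# (K5 / K3,3 subdivisions) are extracted by edge-minimal reduction.

# Demoucron on one biconnected component.
# el: 2-column integer edge matrix (no duplicates, no loops).
# Returns TRUE (with attribute "faces" = number of faces) or FALSE.
demoucron_biconnected <- function(el) {
  verts <- sort(unique(as.vector(el)))
  nv <- length(verts)
  m <- nrow(el)
  if (nv < 3L || m < 3L) return(structure(TRUE, faces = NA_integer_))
  if (m > 3L * nv - 6L) return(FALSE)
  # relabel to 1..nv
  idx <- integer(max(verts))
  idx[verts] <- seq_len(nv)
  a <- idx[el[, 1]]
  b <- idx[el[, 2]]
  adj <- vector("list", nv)
  for (e in seq_len(m)) {
    adj[[a[e]]] <- c(adj[[a[e]]], b[e])
    adj[[b[e]]] <- c(adj[[b[e]]], a[e])
  }
  # edge row lookup by unordered pair
  key <- function(u, v) ifelse(u < v, (u - 1) * nv + v, (v - 1) * nv + u)
  edge_row <- integer(nv * nv)
  edge_row[key(a, b)] <- seq_len(m)

  # --- initial cycle via DFS parent chains ---
  parent <- integer(nv)
  depth <- rep(-1L, nv)
  order_stack <- 1L
  depth[1L] <- 0L
  cyc <- NULL
  stack <- c(1L)
  while (length(stack) && is.null(cyc)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (depth[w] < 0L) {
        depth[w] <- depth[v] + 1L
        parent[w] <- v
        stack <- c(stack, w)
      } else if (w != parent[v]) {
        # walk both parent chains to their meeting point
        pv <- v; chain_v <- v
        while (pv != 1L) { pv <- parent[pv]; chain_v <- c(chain_v, pv) }
        pw <- w; chain_w <- w
        while (pw != 1L) { pw <- parent[pw]; chain_w <- c(chain_w, pw) }
        common <- intersect(chain_v, chain_w)
        # first common vertex along v's chain (deepest common ancestor)
        lca <- chain_v[min(match(common, chain_v))]
        path_v <- chain_v[seq_len(match(lca, chain_v))]
        path_w <- chain_w[seq_len(match(lca, chain_w))]
        cand <- c(path_v, rev(path_w[-length(path_w)]))
        if (length(cand) >= 3L) { cyc <- cand; break }
      }
    }
  }
  if (is.null(cyc)) return(structure(TRUE, faces = NA_integer_))  # forest-like, planar

  in_H <- rep(FALSE, m)
  on_H <- rep(FALSE, nv)
  on_H[cyc] <- TRUE
  for (i in seq_along(cyc)) {
    j <- if (i == length(cyc)) 1L else i + 1L
    in_H[edge_row[key(cyc[i], cyc[j])]] <- TRUE
  }
  faces <- list(cyc, cyc)

  embed_path <- function(path, face_id) {
    # mark path edges/vertices and split faces[[face_id]]
    for (i in seq_len(length(path) - 1L)) {
      in_H[edge_row[key(path[i], path[i + 1L])]] <<- TRUE
    }
    interior <- path[-c(1L, length(path))]
    on_H[interior] <<- TRUE
    f <- faces[[face_id]]
    ia <- match(path[1L], f)
    f2 <- f[c(ia:length(f), seq_len(ia - 1L))]   # rotate so path start is first
    ib <- match(path[length(path)], f2)
    interior <- as.integer(interior)
    face1 <- c(f2[seq_len(ib)], rev(interior))
    face2 <- c(f2[ib:length(f2)], f2[1L], interior)
    faces[[face_id]] <<- face1
    faces[[length(faces) + 1L]] <<- face2
  }

  while (!all(in_H)) {
    # --- fragments ---
    frags <- list()
    rest <- which(!in_H)
    # chords: both endpoints embedded
    chord <- rest[on_H[a[rest]] & on_H[b[rest]]]
    for (e in chord) {
      frags[[length(frags) + 1L]] <- list(type = "chord", edge = e,
                                          attach = c(a[e], b[e]), comp = integer(0))
    }
    # components of the graph induced on unembedded vertices
    free <- which(!on_H)
    if (length(free)) {
      seen <- rep(FALSE, nv)
      for (s in free) {
        if (seen[s]) next
        comp <- s
        seen[s] <- TRUE
        queue <- s
        while (length(queue)) {
          u <- queue[1L]; queue <- queue[-1L]
          for (w in adj[[u]]) {
            if (!on_H[w] && !seen[w]) { seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w) }
          }
        }
        attach <- unique(unlist(lapply(comp, function(u) adj[[u]][on_H[adj[[u]]]])))
        frags[[length(frags) + 1L]] <- list(type = "comp", edge = NA_integer_,
                                            attach = attach, comp = comp)
      }
    }
    if (!length(frags)) break  # nothing left but already-embedded edges
    # --- admissible faces per fragment ---
    adm <- lapply(frags, function(fr) {
      which(vapply(faces, function(f) all(fr$attach %in% f), logical(1)))
    })
    n_adm <- lengths(adm)
    if (any(n_adm == 0L)) return(FALSE)
    pick <- which.min(n_adm)
    fr <- frags[[pick]]
    face_id <- adm[[pick]][1L]
    # --- an alpha-path between two attachments of the fragment ---
    if (fr$type == "chord") {
      path <- c(a[fr$edge], b[fr$edge])
    } else {
      start <- fr$attach[1L]
      par <- integer(nv)
      seen <- rep(FALSE, nv)
      queue <- integer(0)
      target <- NA_integer_; tail_v <- NA_integer_
      for (w in adj[[start]]) {
        if (!on_H[w] && !seen[w] && w %in% fr$comp) {
          seen[w] <- TRUE; par[w] <- start; queue <- c(queue, w)
        }
      }
      while (length(queue) && is.na(target)) {
        u <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[u]]) {
          if (on_H[w] && w != start) { target <- w; tail_v <- u; break }
          if (!on_H[w] && !seen[w]) { seen[w] <- TRUE; par[w] <- u; queue <- c(queue, w) }
        }
      }
      if (is.na(target)) return(FALSE)  # should not happen in a biconnected input
      path <- c(target, tail_v)
      u <- tail_v
      while (par[u] != start) { u <- par[u]; path <- c(path, u) }
      path <- rev(c(path, start))
    }
    embed_path(path, face_id)
  }
  structure(TRUE, faces = length(faces))
}

# normalise input to a deduplicated 2-column integer edge matrix
as_edgelist_input <- function(x, n = NULL) {
  x <- as.matrix(x)
  looks_adjacency <- nrow(x) == ncol(x) && ncol(x) != 2L &&
    all(diag(x) == 0) && max(abs(x - t(x))) < 1e-9
  if (looks_adjacency) {
    W <- x
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    el <- cbind(idx[, 1], idx[, 2])
    n <- nrow(W)
  } else {
    el <- as.matrix(x)
    if (ncol(el) != 2L) stop("edge list must have two columns", call. = FALSE)
    storage.mode(el) <- "integer"
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    el <- unique(el)
    if (is.null(n)) n <- if (nrow(el)) max(el) else 0L
  }
  list(el = el, n = as.integer(n))
}

planar_edgelist <- function(el, n) {
  m <- nrow(el)
  if (m == 0L) return(TRUE)
  if (n >= 3L && m > 3L * n - 6L) return(FALSE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  bc <- igraph::biconnected_components(g)
  for (comp in bc$component_edges) {
    sub <- igraph::ends(g, comp, names = FALSE)
    if (nrow(sub) >= 9L) {  # fewer than 9 edges cannot host K5 or K3,3
      if (isFALSE(demoucron_biconnected(sub))) return(FALSE)
    }
  }
  TRUE
}

# edge-minimal nonplanar subgraph -> Kuratowski subdivision
kuratowski_obstruction <- function(el, n) {
  keep <- rep(TRUE, nrow(el))
  for (e in seq_len(nrow(el))) {
    keep[e] <- FALSE
    if (!planar_edgelist(el[keep, , drop = FALSE], n)) next
    keep[e] <- TRUE
  }
  sub <- el[keep, , drop = FALSE]
  deg <- tabulate(as.vector(sub), nbins = n)
  branch <- deg[deg >= 3L]
  type <- if (length(branch) == 5L && all(branch == 4L)) "K5"
          else if (length(branch) == 6L && all(branch == 3L)) "K3,3"
          else "unclassified"
  list(type = type, edges = sub,
       branch_vertices = which(deg >= 3L))
}

#' Test a graph for planarity
#'
#' Decides planarity with Demoucron's incremental embedding algorithm applied
#' to each biconnected component.  For a nonplanar graph an explicit
#' obstruction — a subdivision of K5 or K3,3, found by edge-minimal
#' reduction — is reported.
#'
#' @param x either a square symmetric adjacency matrix (nonzero off-diagonal
#'   entries are edges) or a 2-column edge matrix.
#' @param n number of vertices (needed only for an edge-matrix input whose
#'   highest-numbered vertex is isolated).
#' @param obstruction if `TRUE` (default) and the graph is nonplanar, extract
#'   the Kuratowski subdivision.
#' @return object of class `"planarity_check"`: `planar` (logical), `n`, `m`,
#'   and for nonplanar input `obstruction` with `type` (`"K5"` or `"K3,3"`),
#'   the subdivision's `edges` and its `branch_vertices`.
#' @examples
#' k5 <- t(combn(5, 2))
#' check_planarity(k5)
#' @export
check_planarity <- function(x, n = NULL, obstruction = TRUE) {
  inp <- as_edgelist_input(x, n)
  planar <- planar_edgelist(inp$el, inp$n)
  obs <- NULL
  if (!planar && obstruction) obs <- kuratowski_obstruction(inp$el, inp$n)
  structure(list(planar = planar, n = inp$n, m = nrow(inp$el), obstruction = obs),
            class = "planarity_check")
}

#' @export
print.planarity_check <- function(x, ...) {
  cat(sprintf("Graph on %d vertices, %d edges: %s\n", x$n, x$m,
              if (x$planar) "planar" else "NOT planar"))
  if (!is.null(x$obstruction)) {
    cat(sprintf("  obstruction: %s subdivision on branch vertices {%s}\n",
                x$obstruction$type,
                paste(x$obstruction$branch_vertices, collapse = ", ")))
  }
  invisible(x)
}
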