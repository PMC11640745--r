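# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the previous
#' RNG state so callers never clobber the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# coerce the various network containers to a weighted adjacency matrix
as_adjacency <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("adjacency matrix must be square", call. = FALSE)
    return(x)
  }
  as.matrix(x)
}

check_symmetric_nonneg <- function(W, name = "W", tol = 1e-10) {
  if (any(!is.finite(W))) stop(sprintf("%s contains non-finite entries", name), call. = FALSE)
  if (max(abs(W - t(W))) > tol) stop(sprintf("%s must be symmetric", name), call. = FALSE)
  if (any(diag(W) != 0)) stop(sprintf("%s must have a zero diagonal", name), call. = FALSE)
  invisible(TRUE)
}

# population standard deviation (divides by n, not n - 1)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
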