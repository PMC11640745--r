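#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a two-class feature table by interpolating synthetic minority
#' rows: each synthetic sample is `x_i + delta * (x_nn - x_i)` where `x_nn`
#' is one of the `k` Euclidean nearest neighbours of `x_i` within the
#' minority class and `delta ~ U(0, 1)`.  Generation continues until the
#' class counts are equal.
#'
#' @param X numeric feature matrix or data.frame (rows = samples).
#' @param y class labels (two classes).
#' @param k number of minority-class neighbours (default 5); reduced with a
#'   warning when the minority class has `<= k` rows.
#' @param seed integer seed.
#' @param delta optional fixed interpolation scalar in `[0, 1]` (overrides the
#'   uniform draw; intended for deterministic fixtures).
#' @return object of class `"smote_result"`: `X` (augmented matrix), `y`
#'   (augmented labels), `synthetic` (logical flag per row), `base_index` and
#'   `neighbor_index` (minority-row provenance of each synthetic row, `NA` for
#'   originals), `k`, `seed`.
#' @examples
#' sm <- smote(rbind(c(0, 0), c(1, 1), matrix(5, 6, 2)),
#'             c("a", "a", rep("b", 6)), k = 1, seed = 1, delta = 0.5)
#' table(sm$y)
#' @export
smote <- function(X, y, k = 5, seed = 1, delta = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) != 2L) stop("SMOTE needs exactly two classes", call. = FALSE)
  counts <- table(y)
  if (counts[1] == counts[2]) {
    return(structure(list(X = X, y = y, synthetic = rep(FALSE, nrow(X)),
                          base_index = rep(NA_integer_, nrow(X)),
                          neighbor_index = rep(NA_integer_, nrow(X)),
                          k = k, seed = seed),
                     class = "smote_result"))
  }
  minority <- names(counts)[which.min(counts)]
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  n_new <- max(counts) - n_min
  if (n_min < 2L) stop("minority class needs at least 2 rows", call. = FALSE)
  if (k >= n_min) {
    warning(sprintf("k reduced from %d to %d (minority class has %d rows)",
                    k, n_min - 1L, n_min))
    k <- n_min - 1L
  }
  Xm <- X[min_idx, , drop = FALSE]
  Dm <- as.matrix(stats::dist(Xm))
  diag(Dm) <- Inf
  nn <- matrix(0L, n_min, k)
  for (i in seq_len(n_min)) nn[i, ] <- order(Dm[i, ])[seq_len(k)]
  synth <- with_seed(seed, {
    base <- sample(rep_len(seq_len(n_min), n_new))
    pick <- vapply(base, function(i) nn[i, sample.int(k, 1L)], integer(1))
    d <- if (is.null(delta)) stats::runif(n_new) else rep(delta, n_new)
    list(rows = Xm[base, , drop = FALSE] +
           d * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE]),
         base = base, pick = pick)
  })
  structure(list(X = rbind(X, synth$rows),
                 y = c(y, rep(minority, n_new)),
                 synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)),
                 base_index = c(rep(NA_integer_, nrow(X)), min_idx[synth$base]),
                 neighbor_index = c(rep(NA_integer_, nrow(X)), min_idx[synth$pick]),
                 k = k, seed = seed),
            class = "smote_result")
}

#' @export
print.smote_result <- function(x, ...) {
  cat(sprintf("SMOTE: %d rows (%d synthetic), k = %d, balanced counts: %s\n",
              nrow(x$X), sum(x$synthetic), x$k,
              paste(sprintf("%s=%d", names(table(x$y)), table(x$y)), collapse = ", ")))
  invisible(x)
}
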