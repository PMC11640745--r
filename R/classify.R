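#' Z-score standardisation with held-out transform
#'
#' Estimates per-feature mean and population standard deviation on `fit_rows`
#' only and applies the transform to all rows, so held-out rows never
#' influence the parameters.  Zero-spread features are centred but not scaled,
#' with a warning.
#'
#' @param X numeric feature matrix.
#' @param fit_rows row indices used to estimate the parameters (default: all).
#' @return list with `X` (standardised matrix), `mu`, `sigma`.
#' @examples
#' zscore_standardize(cbind(a = c(1, 2, 3)))$X
#' @export
zscore_standardize <- function(X, fit_rows = seq_len(nrow(X))) {
  X <- as.matrix(X)
  mu <- colMeans(X[fit_rows, , drop = FALSE])
  sigma <- apply(X[fit_rows, , drop = FALSE], 2, sd_pop)
  if (any(sigma == 0)) {
    warning("zero-spread features left centred: ",
            paste(colnames(X)[sigma == 0], collapse = ", "))
    sigma[sigma == 0] <- 1
  }
  list(X = sweep(sweep(X, 2, mu), 2, sigma, "/"), mu = mu, sigma = sigma)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 from true/false positive/negative
#' counts.  Precision (and hence F1) is `NA` when nothing was predicted
#' positive.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return named numeric vector.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation of a neural classifier.  Within each
#' fold, features are standardised on the training rows only, the training
#' rows (never the test fold) are SMOTE-balanced, the model is trained, and
#' the untouched test fold is scored at threshold 0.5.  The positive class is
#' the second factor level of `y`.
#'
#' @param X feature matrix; @param y two-level labels.
#' @param spec a [model_spec()].
#' @param folds number of folds (default 10); every fold must contain both
#'   classes or the split aborts with a stratification error.
#' @param seed seed for the fold assignment and per-fold training/SMOTE seeds.
#' @param smote_k SMOTE neighbour count.
#' @param apply_smote set `FALSE` to skip balancing (for nulls/diagnostics).
#' @return object of class `"cv_report"`: `per_fold` metrics data.frame,
#'   summed `confusion` counts, `mean_metrics`, `spec`, `folds`, `seed`,
#'   per-fold standardisation parameters.
#' @export
train_evaluate_cv <- function(X, y, spec, folds = 10, seed = 1, smote_k = 5,
                              apply_smote = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly two classes", call. = FALSE)
  pos <- levels(y)[2]
  fold_id <- stratified_folds(as.character(y), folds, seed)
  for (f in seq_len(folds)) {
    if (length(unique(y[fold_id == f])) < 2L) {
      stop(sprintf("stratification failure: fold %d lacks a class (class counts %s)",
                   f, paste(table(y), collapse = "/")), call. = FALSE)
    }
  }
  per_fold <- vector("list", folds)
  conf <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  std_params <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    st <- zscore_standardize(X, fit_rows = train)
    std_params[[f]] <- list(mu = st$mu, sigma = st$sigma)
    Xtr <- st$X[train, , drop = FALSE]
    ytr <- as.character(y[train])
    if (apply_smote && length(unique(table(ytr))) > 1L) {
      sm <- smote(Xtr, ytr, k = smote_k, seed = seed * 131 + f)
      Xtr <- sm$X
      ytr <- sm$y
    }
    fold_spec <- spec
    fold_spec$seed <- as.integer((spec$seed * 977 + f) %% 2147483647)
    fit <- train_network(Xtr, factor(ytr, levels = levels(y)), fold_spec)
    pred <- predict(fit, st$X[test, , drop = FALSE], type = "class")
    truth <- as.integer(y[test] == pos)
    tp <- sum(pred == 1 & truth == 1)
    tn <- sum(pred == 0 & truth == 0)
    fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    conf <- conf + c(tp = tp, tn = tn, fp = fp, fn = fn)
    per_fold[[f]] <- data.frame(fold = f, t(classification_metrics(tp, tn, fp, fn)),
                                n_test = length(test))
  }
  per_fold <- do.call(rbind, per_fold)
  mean_metrics <- colMeans(per_fold[, c("accuracy", "precision", "recall", "f1")],
                           na.rm = TRUE)
  structure(list(per_fold = per_fold, confusion = conf,
                 mean_metrics = mean_metrics, spec = spec, folds = folds,
                 seed = seed, positive_class = pos, std_params = std_params),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold stratified CV (%s, positive class %s)\n", x$folds,
              x$spec$architecture, x$positive_class))
  print(round(x$per_fold, digits), row.names = FALSE)
  cat("\nAggregated confusion: ",
      sprintf("TP=%d TN=%d FP=%d FN=%d", x$confusion["tp"], x$confusion["tn"],
              x$confusion["fp"], x$confusion["fn"]), "\n")
  cat("Mean metrics: ",
      paste(sprintf("%s=%.4f", names(x$mean_metrics), x$mean_metrics),
            collapse = "  "), "\n")
  invisible(x)
}
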