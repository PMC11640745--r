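#' Group statistical battery on a feature table
#'
#' For each feature: Shapiro-Wilk normality within each group, Levene's test
#' of variance homogeneity across groups (mean-centred, i.e. the classical
#' form), a two-sided Mann-Whitney U test with rank-biserial effect size
#' `r = 1 - 2U/(n1*n2)`, and Bonferroni adjustment `p_adj = min(1, m * p)`
#' over the `m` features tested.  Exact Mann-Whitney p-values are used for
#' small tie-free samples (both groups `<= 8`); otherwise the
#' normal approximation with tie correction.
#'
#' Constant features cannot be tested; their rows are flagged and carry `NA`
#' statistics.
#'
#' @param X numeric feature matrix/data.frame (columns = features).
#' @param y group labels, exactly two levels, `>= 3` rows each.
#' @param alpha significance level for the significance flags.
#' @return object of class `"group_stat_report"` with data.frames `shapiro`
#'   (feature, group, W, p), `levene` (feature, F, p), `mann_whitney`
#'   (feature, U, p, p_bonferroni, effect_size, significant), the feature
#'   `correlations` matrix, `alpha` and group sizes.
#' @examples
#' X <- cbind(a = c(1:6, 8:13), b = rnorm(12))
#' y <- rep(c("HC", "PD"), each = 6)
#' run_group_tests(X, y)
#' @export
run_group_tests <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly two groups", call. = FALSE)
  g1 <- levels(y)[1]
  g2 <- levels(y)[2]
  if (min(table(y)) < 3L) stop("each group needs >= 3 rows", call. = FALSE)
  feats <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  m <- length(feats)

  shapiro_rows <- list()
  lev <- mw <- vector("list", m)
  for (j in seq_len(m)) {
    xj <- X[, j]
    constant <- sd_pop(xj) == 0
    for (g in c(g1, g2)) {
      v <- xj[y == g]
      ok <- !constant && sd_pop(v) > 0 && length(v) >= 3L && length(v) <= 5000L
      sw <- if (ok) stats::shapiro.test(v) else NULL
      shapiro_rows[[length(shapiro_rows) + 1L]] <- data.frame(
        feature = feats[j], group = g,
        W = if (ok) unname(sw$statistic) else NA_real_,
        p = if (ok) sw$p.value else NA_real_,
        constant = constant, stringsAsFactors = FALSE)
    }
    if (constant) {
      lev[[j]] <- data.frame(feature = feats[j], F = NA_real_, p = NA_real_,
                             constant = TRUE, stringsAsFactors = FALSE)
      mw[[j]] <- data.frame(feature = feats[j], U = NA_real_, p = NA_real_,
                            effect_size = NA_real_, constant = TRUE,
                            stringsAsFactors = FALSE)
      next
    }
    lt <- car::leveneTest(xj ~ y, center = mean)
    lev[[j]] <- data.frame(feature = feats[j], F = lt[1, "F value"],
                           p = lt[1, "Pr(>F)"], constant = FALSE,
                           stringsAsFactors = FALSE)
    x1 <- xj[y == g1]
    x2 <- xj[y == g2]
    exact <- length(x1) <= 8L && length(x2) <= 8L && !any(duplicated(c(x1, x2)))
    wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = exact, correct = !exact))
    U <- unname(wt$statistic)   # number of (x1 > x2) pairs, ties counted half
    r <- 1 - 2 * U / (length(x1) * length(x2))
    mw[[j]] <- data.frame(feature = feats[j], U = U, p = wt$p.value,
                          effect_size = r, constant = FALSE,
                          stringsAsFactors = FALSE)
  }
  mwd <- do.call(rbind, mw)
  mwd$p_bonferroni <- pmin(1, m * mwd$p)
  mwd$significant <- !is.na(mwd$p_bonferroni) & mwd$p_bonferroni < alpha
  structure(list(shapiro = do.call(rbind, shapiro_rows),
                 levene = do.call(rbind, lev),
                 mann_whitney = mwd[, c("feature", "U", "p", "p_bonferroni",
                                        "effect_size", "significant", "constant")],
                 correlations = feature_correlations(X),
                 alpha = alpha, groups = c(g1, g2),
                 n = as.integer(table(y))),
            class = "group_stat_report")
}

#' @export
print.group_stat_report <- function(x, digits = 4, ...) {
  cat(sprintf("Group statistical battery: %s (n=%d) vs %s (n=%d), alpha = %g\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2], x$alpha))
  cat("\nMann-Whitney (Bonferroni-adjusted):\n")
  print(format(x$mann_whitney, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix of the features
#'
#' @param X numeric feature matrix/data.frame, `>= 3` rows.
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   features give `NA` rows/columns with a warning.
#' @export
feature_correlations <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need >= 3 rows", call. = FALSE)
  const <- apply(X, 2, sd_pop) == 0
  if (any(const)) {
    warning("zero-variance features: ", paste(colnames(X)[const], collapse = ", "))
  }
  suppressWarnings(stats::cor(X))
}

#' Run the battery before and after SMOTE balancing
#'
#' Emits the statistical battery twice: on the raw (pre-balance) table — the
#' statistically sound default, since synthetic rows are not independent
#' observations — and on the SMOTE-augmented table, mirroring analyses that
#' report tests after balancing.
#'
#' @param X feature matrix; @param y two-level group labels.
#' @param k,seed SMOTE parameters.
#' @param alpha significance level.
#' @return list with elements `pre_smote` and `post_smote` (both
#'   `"group_stat_report"`) and the `"smote_result"` used.
#' @export
group_battery <- function(X, y, k = 5, seed = 1, alpha = 0.05) {
  sm <- smote(X, y, k = k, seed = seed)
  list(pre_smote = run_group_tests(X, y, alpha = alpha),
       post_smote = run_group_tests(sm$X, sm$y, alpha = alpha),
       smote = sm)
}
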