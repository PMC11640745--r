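#' Positive and negative partial sums of a series
#'
#' Splits the first differences of a series into their positive and negative
#' parts, either as raw increments (`max(diff(x), 0)` and `min(diff(x), 0)`)
#' or as their running (cumulative) sums, the form used in most of the
#' distributed-lag literature.
#'
#' In `"increment"` mode `pos - abs(neg)` reconstructs `diff(x)` exactly; in
#' `"cumulative"` mode `pos + neg` reconstructs `x - x[1]`.
#'
#' @param x numeric series, length >= 2. A constant series is legal: both
#'   branches are then identically zero.
#' @param mode `"increment"` (default) or `"cumulative"`.
#' @return list with components `pos` and `neg`, each of length `length(x) - 1`,
#'   aligned with time points `2:length(x)` of the input.
#' @examples
#' decompose_partial_sums(c(0, 1, -1, 2))
#' decompose_partial_sums(c(0, 1, -1, 2), mode = "cumulative")
#' @export
decompose_partial_sums <- function(x, mode = c("increment", "cumulative")) {
  mode <- match.arg(mode)
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be a numeric series of length >= 2", call. = FALSE)
  }
  d <- diff(x)
  pos <- pmax(d, 0)
  neg <- pmin(d, 0)
  if (mode == "cumulative") {
    pos <- cumsum(pos)
    neg <- cumsum(neg)
  }
  list(pos = pos, neg = neg, mode = mode)
}

# short-run / long-run aggregation from a coefficient set.  The long-run
# denominator 1 - sum(phi) is floored at `denom_floor` and the ratios clipped
# at +/- `longrun_cap` so near-unit-root fits cannot explode the score.
nardl_dependency <- function(phi, bpos, bneg,
                             cd_form = c("text", "literal"),
                             denom_floor = 1e-3, longrun_cap = 1e3) {
  cd_form <- match.arg(cd_form)
  sp <- sum(bpos)
  sn <- sum(bneg)
  den <- 1 - sum(phi)
  floored <- abs(den) < denom_floor
  den_c <- if (floored) denom_floor * ifelse(den < 0, -1, 1) else den
  lp <- sp / den_c
  ln <- sn / den_c
  clipped <- abs(lp) > longrun_cap || abs(ln) > longrun_cap
  lp <- max(min(lp, longrun_cap), -longrun_cap)
  ln <- max(min(ln, longrun_cap), -longrun_cap)
  cd <- if (cd_form == "text") (sp + lp) - (sn + ln) else sp + lp - sn + ln
  list(sp = sp, sn = sn, lp = lp, ln = ln, cd = cd,
       longrun_flagged = floored || clipped)
}

#' Combined dependency from known coefficients
#'
#' Pure arithmetic: given autoregressive and asymmetric distributed-lag
#' coefficients, computes the short-run sums SP and SN, the long-run ratios
#' LP = SP / (1 - sum(phi)) and LN = SN / (1 - sum(phi)), and the combined
#' dependency CD = (SP + LP) - (SN + LN).
#'
#' @param phi autoregressive coefficients (length p).
#' @param bpos,bneg positive- and negative-branch coefficients (length p + 1,
#'   lags 0..p).
#' @param cd_form `"text"` (default) aggregates the positive terms and
#'   subtracts the aggregated negative terms; `"literal"` uses the alternative
#'   reading SP + LP - SN + LN.
#' @param denom_floor smallest admissible `|1 - sum(phi)|`; below it the
#'   long-run ratios are computed against the floor and flagged.
#' @param longrun_cap clip value for LP and LN.
#' @return list with `sp`, `sn`, `lp`, `ln`, `cd` and `longrun_flagged`.
#' @examples
#' nardl_cd(phi = 0.5, bpos = 0.6, bneg = -0.2)
#' @export
nardl_cd <- function(phi, bpos, bneg, cd_form = c("text", "literal"),
                     denom_floor = 1e-3, longrun_cap = 1e3) {
  nardl_dependency(phi, bpos, bneg, cd_form = match.arg(cd_form),
                   denom_floor = denom_floor, longrun_cap = longrun_cap)
}

#' Fit an asymmetric distributed-lag (NARDL) dependency model
#'
#' Regresses a response series on its own lags and on the positive and
#' negative partial sums of a driver series,
#' \deqn{y_t = \alpha + \sum_{i=1}^p \phi_i y_{t-i}
#'   + \sum_{i=0}^p \beta^+_i x^+_{t-i}
#'   + \sum_{i=0}^p \beta^-_i x^-_{t-i} + \epsilon_t,}
#' by ordinary least squares on the lag-trimmed sample (the first `p + 1`
#' time points are dropped; no padding).  From the fitted coefficients it
#' aggregates the short-run dependencies SP = sum(beta+), SN = sum(beta-),
#' the long-run dependencies LP, LN, and the scalar combined dependency CD.
#'
#' A rank-deficient design is not an error: the fit is flagged degenerate and
#' CD is set to 0 so that pairwise network assembly can continue and surface
#' the flag in its QC table.
#'
#' @param y response series.
#' @param x driver series, same length as `y`.
#' @param p lag order (default 2).
#' @param mode partial-sum mode, see [decompose_partial_sums()].
#' @param cd_form,denom_floor,longrun_cap see [nardl_cd()].
#' @return an object of class `"nardl"` with components `coefficients`
#'   (named `alpha`, `phi1..phip`, `bpos0..bposp`, `bneg0..bnegp`), `sp`,
#'   `sn`, `lp`, `ln`, `cd`, `residuals`, `fitted.values`, `sigma2`, `n_eff`,
#'   `p`, `mode`, `degenerate`, `longrun_flagged` and `vcov`.
#' @examples
#' sim <- simulate_nardl_pair(nardl_truth(phi = c(0.3, 0.1),
#'                                        bpos = c(0.4, 0.1, 0),
#'                                        bneg = c(-0.2, 0, 0.1)),
#'                            n = 500, seed = 1)
#' fit <- nardl(sim$y, sim$x, p = 2)
#' coef(fit)
#' fit$cd
#' @export
nardl <- function(y, x, p = 2, mode = c("increment", "cumulative"),
                  cd_form = c("text", "literal"),
                  denom_floor = 1e-3, longrun_cap = 1e3) {
  mode <- match.arg(mode)
  cd_form <- match.arg(cd_form)
  p <- stop_if_not_scalar_count(p, "p", min = 1L)
  if (length(y) != length(x)) stop("`y` and `x` must have equal length", call. = FALSE)
  n <- length(y)
  k <- 3L * p + 3L           # alpha + p AR + (p + 1) per branch
  n_eff <- n - p - 1L
  if (n_eff < 3L * k) {
    stop(sprintf("series too short: need length - p - 1 >= %d observations for p = %d",
                 3L * k, p), call. = FALSE)
  }
  ps <- decompose_partial_sums(x, mode = mode)
  # partial-sum index i corresponds to time point i + 1
  tt <- (p + 2L):n
  X <- matrix(0, length(tt), k)
  X[, 1L] <- 1
  for (i in seq_len(p)) X[, 1L + i] <- y[tt - i]
  for (i in 0:p) {
    X[, 2L + p + i] <- ps$pos[tt - i - 1L]
    X[, 3L + 2L * p + i] <- ps$neg[tt - i - 1L]
  }
  yy <- y[tt]
  qx <- qr(X)
  cn <- c("alpha", paste0("phi", seq_len(p)), paste0("bpos", 0:p), paste0("bneg", 0:p))
  degenerate <- qx$rank < k
  if (degenerate) {
    cf <- rep(NA_real_, k)
    names(cf) <- cn
    out <- list(coefficients = cf, sp = NA_real_, sn = NA_real_,
                lp = NA_real_, ln = NA_real_, cd = 0,
                residuals = rep(NA_real_, length(yy)),
                fitted.values = rep(NA_real_, length(yy)),
                sigma2 = NA_real_, vcov = NULL,
                n_eff = n_eff, p = p, mode = mode, cd_form = cd_form,
                degenerate = TRUE, longrun_flagged = FALSE,
                call = match.call())
    class(out) <- "nardl"
    return(out)
  }
  cf <- qr.coef(qx, yy)
  names(cf) <- cn
  fitted <- drop(X %*% cf)
  res <- yy - fitted
  sigma2 <- sum(res^2) / (n_eff - k)
  XtXinv <- chol2inv(qr.R(qx))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(cn, cn)
  dep <- nardl_dependency(cf[2:(p + 1L)], cf[(p + 2L):(2L * p + 2L)],
                          cf[(2L * p + 3L):k],
                          cd_form = cd_form, denom_floor = denom_floor,
                          longrun_cap = longrun_cap)
  out <- list(coefficients = cf, sp = dep$sp, sn = dep$sn, lp = dep$lp,
              ln = dep$ln, cd = dep$cd, residuals = res,
              fitted.values = fitted, sigma2 = sigma2, vcov = vc,
              n_eff = n_eff, p = p, mode = mode, cd_form = cd_form,
              degenerate = FALSE, longrun_flagged = dep$longrun_flagged,
              call = match.call())
  class(out) <- "nardl"
  out
}

#' @export
print.nardl <- function(x, digits = 4, ...) {
  cat("Asymmetric distributed-lag (NARDL) fit\n")
  cat(sprintf("  lag order p = %d, %s partial sums, n_eff = %d\n",
              x$p, x$mode, x$n_eff))
  if (x$degenerate) {
    cat("  DEGENERATE fit (rank-deficient design); CD set to 0\n")
    return(invisible(x))
  }
  print(round(x$coefficients, digits))
  cat(sprintf("  SP = %.4f  SN = %.4f  LP = %.4f  LN = %.4f\n",
              x$sp, x$sn, x$lp, x$ln))
  cat(sprintf("  Combined dependency CD = %.4f%s\n", x$cd,
              if (x$longrun_flagged) "  [long-run denominator floored/clipped]" else ""))
  invisible(x)
}

#' @export
coef.nardl <- function(object, ...) object$coefficients

#' @export
residuals.nardl <- function(object, ...) object$residuals

#' @export
fitted.nardl <- function(object, ...) object$fitted.values

#' @export
vcov.nardl <- function(object, ...) object$vcov

#' @export
summary.nardl <- function(object, ...) {
  if (object$degenerate) {
    out <- list(fit = object, coef_table = NULL)
    class(out) <- "summary.nardl"
    return(out)
  }
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df = object$n_eff - length(se))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.nardl"
  out
}

#' @export
print.summary.nardl <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$coef_table)) {
    cat("\nCoefficients:\n")
    stats::printCoefmat(x$coef_table, ...)
  }
  invisible(x)
}

#' Predict from a fitted NARDL model
#'
#' One-step-ahead fitted values on a new `(y, x)` pair using the estimated
#' coefficients; the first `p + 1` time points of the new series are used only
#' as lags.
#'
#' @param object a fitted `"nardl"` model.
#' @param y,x new response and driver series (defaults: refit sample not kept,
#'   so both are required).
#' @param ... unused.
#' @return numeric vector of length `length(y) - p - 1`.
#' @export
predict.nardl <- function(object, y, x, ...) {
  if (object$degenerate) stop("cannot predict from a degenerate fit", call. = FALSE)
  p <- object$p
  ps <- decompose_partial_sums(x, mode = object$mode)
  tt <- (p + 2L):length(y)
  cf <- object$coefficients
  out <- rep(cf[["alpha"]], length(tt))
  for (i in seq_len(p)) out <- out + cf[[paste0("phi", i)]] * y[tt - i]
  for (i in 0:p) {
    out <- out + cf[[paste0("bpos", i)]] * ps$pos[tt - i - 1L] +
      cf[[paste0("bneg", i)]] * ps$neg[tt - i - 1L]
  }
  out
}

#' Simulate new response series from a fitted NARDL model
#'
#' Uses the fitted coefficients and residual variance as generating truth and
#' draws fresh driver/response pairs with [simulate_nardl_pair()].
#'
#' @param object a fitted `"nardl"` model.
#' @param nsim number of series pairs to draw.
#' @param seed integer seed.
#' @param n length of each simulated series.
#' @param ... unused.
#' @return a list of `nsim` elements, each a list with `x` and `y`.
#' @export
simulate.nardl <- function(object, nsim = 1, seed = 1, n = 500, ...) {
  if (object$degenerate) stop("cannot simulate from a degenerate fit", call. = FALSE)
  p <- object$p
  cf <- object$coefficients
  truth <- nardl_truth(alpha = cf[["alpha"]],
                       phi = cf[paste0("phi", seq_len(p))],
                       bpos = cf[paste0("bpos", 0:p)],
                       bneg = cf[paste0("bneg", 0:p)],
                       sigma = sqrt(object$sigma2))
  lapply(seq_len(nsim), function(i) {
    sim <- simulate_nardl_pair(truth, n = n, seed = seed + i - 1L)
    list(x = sim$x, y = sim$y)
  })
}
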