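#' Simple linear regression between two per-SNP vectors
#'
#' Ordinary least squares of `y` on `x` over pairwise-complete SNPs,
#' reporting the signed correlation `r` (sign of the slope), r-squared, the
#' coefficient table, and the model F test.
#'
#' @param y per-SNP response vector.
#' @param x per-SNP predictor vector.
#' @return list of class `simple_reg`: `r`, `r2`, `coefficients`, `f`,
#'   `df`, `p`, `n`.
#' @export
fit_simple_regression <- function(y, x) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stopf("fewer than 3 complete (x, y) pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0) stopf("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r <- sqrt(sm$r.squared) * sign(stats::coef(fit)[["x"]])
  f <- unname(sm$fstatistic)
  structure(list(
    r = r, r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    coefficients = stats::coef(sm), f = f[1], df = f[2:3],
    p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    n = length(x)), class = "simple_reg")
}

#' @export
print.simple_reg <- function(x, ...) {
  cat(sprintf("simple regression: r = %.3f, r2 = %.3f, F(%d, %d) = %.1f, p = %.3g, n = %d\n",
              x$r, x$r2, x$df[1], x$df[2], x$f, x$p, x$n))
  invisible(x)
}

#' Forward/backward stepwise multiple regression by AIC
#'
#' Fits the full Gaussian linear model of a per-SNP response on the candidate
#' predictors over complete-case SNP rows, then searches in both directions
#' by AIC (`n log(RSS/n) + 2k`, `k` counting all fitted coefficients),
#' starting from the full model. Duplicated predictor columns are reduced to
#' the first occurrence before fitting. Returns the selected model with
#' per-coefficient standard errors and t statistics, adjusted R-squared, and
#' the model F test.
#'
#' @param y per-SNP response vector.
#' @param X data frame (or matrix) of candidate per-SNP predictors.
#' @return list of class `stepwise_reg`: `retained`, `coefficients`,
#'   `adj_r2`, `f`, `df`, `p`, `aic`, `aic_full`, `n`, `dropped_duplicates`,
#'   and the underlying `fit`.
#' @export
stepwise_aic <- function(y, X) {
  X <- as.data.frame(X)
  if (!ncol(X)) stopf("no candidate predictors")
  dup <- duplicated(as.list(X))
  dropped <- names(X)[dup]
  X <- X[!dup]
  dat <- data.frame(y = y, X, check.names = FALSE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= ncol(X) + 1) stopf("too few complete rows for the design")
  if (all(vapply(X, function(v) stats::var(v, na.rm = TRUE) == 0, logical(1))))
    stopf("all predictors are constant")

  full <- stats::lm(y ~ ., data = dat)
  sel <- stats::step(full, direction = "both", trace = 0)
  sm <- summary(sel)
  retained <- attr(stats::terms(sel), "term.labels")
  fstat <- sm$fstatistic
  structure(list(
    retained = retained,
    coefficients = stats::coef(sm),
    adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
    f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df = if (is.null(fstat)) c(NA, NA) else unname(fstat[2:3]),
    p = if (is.null(fstat)) NA_real_ else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    aic = stats::extractAIC(sel)[2], aic_full = stats::extractAIC(full)[2],
    n = n, dropped_duplicates = dropped, fit = sel), class = "stepwise_reg")
}

#' @export
print.stepwise_reg <- function(x, ...) {
  cat(sprintf("stepwise model (%d rows): %s\n", x$n,
              if (length(x$retained)) paste(x$retained, collapse = " + ")
              else "(intercept only)"))
  cat(sprintf("  adj R2 = %.4f, F(%g, %g) = %.1f, p = %.3g, AIC = %.1f\n",
              x$adj_r2, x$df[1], x$df[2], x$f, x$p, x$aic))
  invisible(x)
}
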