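#' Fisher Z transform of correlation coefficients
#'
#' Variance-stabilizing `atanh` transform.  Correlations with `|r| > 1` are
#' rejected; values within machine reach of +/-1 are clipped to
#' `+/-(1 - clip_eps)` so the transform stays finite (e.g. a voxel correlated
#' with itself, or a seed map evaluated at a seed voxel).
#'
#' @param r numeric vector of correlation coefficients.
#' @param clip_eps clipping margin; values are clipped to `1 - clip_eps` in
#'   absolute value before `atanh`.  Default `1e-7`.
#' @return numeric vector of Fisher Z values, same length as `r`.
#' @export
fisher_z <- function(r, clip_eps = 1e-7) {
  if (!is.numeric(r)) stop("`r` must be numeric")
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) {
    stop(sprintf("correlation out of range: |r| = %.6g exceeds 1",
                 max(abs(r[bad]))))
  }
  lim <- 1 - clip_eps
  atanh(pmin(pmax(r, -lim), lim))     # r first so dim attributes survive
}

#' Paired-sample t-test (safe vs. threat)
#'
#' Classical paired t on per-subject condition values:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = threat - safe` and
#' `df = n - 1`.  Computed directly from the textbook formula (the test
#' suite checks it against [stats::t.test()]).
#'
#' @param x per-subject differences, or the first condition if `y` is given.
#' @param y optional second condition; differences are `y - x`, so with
#'   `x = safe, y = threat` a positive t means threat > safe.
#' @return list with `statistic`, `df`, `p.value`, `mean_diff`.
#' @export
paired_t <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    as.numeric(y) - as.numeric(x)
  }
  if (anyNA(d)) stop("missing pairs are not allowed")
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of paired differences; t is undefined")
  tval <- mean(d) / (s / sqrt(n))
  df <- n - 1L
  list(statistic = tval, df = df,
       p.value = 2 * stats::pt(-abs(tval), df),
       mean_diff = mean(d))
}

#' Pearson correlation with test
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `r`, `df` (= n - 2), `p.value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input; correlation undefined")
  r <- sum(scale(x) * scale(y)) / (n - 1)
  df <- n - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p.value = 2 * stats::pt(-abs(tval), df))
}

#' ANCOVA on paired difference scores
#'
#' Tests the condition effect after adjusting for a per-subject covariate
#' (e.g. the safe-minus-threat difference in retained trial counts, or
#' residual motion).  The model is an OLS regression of the difference
#' scores on an intercept plus the centered covariate; the reported F is
#' the squared t of the intercept, i.e. the adjusted condition effect,
#' with `df = (1, n - 2)`.
#'
#' @param d per-subject difference scores (threat - safe).
#' @param covariate per-subject covariate, same length as `d`.
#' @return list with `F`, `df1`, `df2`, `p.value`, `adjusted_mean`.
#' @export
ancova_on_differences <- function(d, covariate) {
  n <- length(d)
  if (length(covariate) != n) stop("covariate length must match d")
  if (n < 3L) stop("need at least 3 subjects")
  if (stats::sd(covariate) == 0)
    stop("covariate is constant (collinear with intercept)")
  cc <- covariate - mean(covariate)
  X <- cbind(1, cc)
  fit <- stats::lm.fit(X, d)
  rss <- sum(fit$residuals^2)
  df2 <- n - 2L
  sigma2 <- rss / df2
  # centered covariate => (X'X) diagonal; var(b0) = sigma2 / n
  b0 <- fit$coefficients[[1L]]
  Fval <- b0^2 / (sigma2 / n)
  list(F = Fval, df1 = 1L, df2 = df2,
       p.value = stats::pf(Fval, 1, df2, lower.tail = FALSE),
       adjusted_mean = b0)
}

#' Within-subject standard error of the mean
#'
#' Repeated-measures error bars: each subject's rows are shifted so that
#' subject means coincide with the grand mean (removing between-subject
#' offsets), the per-condition SEM of the normalized values is computed,
#' and the Morey correction factor `sqrt(C / (C - 1))` applied (on by
#' default).
#'
#' @param mat numeric matrix, subjects x conditions, no missing values.
#' @param morey apply the Morey bias correction (default TRUE).
#' @return numeric vector of per-condition SEMs (named if `mat` has
#'   column names).
#' @export
within_subject_sem <- function(mat, morey = TRUE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete")
  C <- ncol(mat)
  if (C < 2L) stop("need at least 2 conditions")
  n <- nrow(mat)
  norm <- mat - rowMeans(mat) + mean(mat)
  sem <- apply(norm, 2L, stats::sd) / sqrt(n)
  if (morey) sem <- sem * sqrt(C / (C - 1))
  sem
}
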