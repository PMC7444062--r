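#' Pearson correlation with pairwise deletion
#'
#' Sample Pearson correlation with a two-sided p-value from the t
#' distribution on n - 2 degrees of freedom. Rows with a missing value in
#' either column are dropped pairwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @examples
#' apa_pearson(1:4, c(2, 4, 6, 8))
#' @export
apa_pearson <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance column: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(r = r, p = p, n = n)
}

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on the covariate design (with intercept) by
#' least squares, then correlates the residuals; the p-value uses
#' `n - 2 - k` degrees of freedom for `k` covariate columns. Character or
#' factor covariates are expanded to dummy columns. With an empty
#' covariate set this reduces exactly to [apa_pearson()].
#'
#' @param x,y Numeric vectors.
#' @param covariates A data frame of covariate columns (possibly
#'   zero-column), row-aligned with `x` and `y`.
#' @return A one-row tibble: `r`, `p`, `n`, `df`.
#' @export
apa_partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    out <- apa_pearson(x, y)
    out$df <- out$n - 2L
    return(out)
  }
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]
  y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  Z <- stats::model.matrix(~ ., data = covariates)
  k <- ncol(Z) - 1L
  n <- length(x)
  if (n < k + 3) {
    stop("need at least ", k + 3, " complete rows for ", k, " covariate(s)",
         call. = FALSE)
  }
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    bad <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  # residual variance at rounding-noise level counts as zero
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1e-300)) {
    stop("zero-variance residuals: partial correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = df)
  tibble::tibble(r = r, p = p, n = n, df = df)
}

#' Intraclass correlation: two-way mixed, absolute agreement, single measure
#'
#' The single-measure absolute-agreement ICC from the two-way ANOVA mean
#' squares of an n-subjects-by-k-sessions matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (subject), column
#' (session) and error mean squares. Absolute agreement penalizes both
#' inconsistency and systematic session offsets. The 95% confidence
#' interval uses the standard F-based formulas with Satterthwaite degrees
#' of freedom. Rows with any missing cell are dropped listwise.
#'
#' @param measurements An n x k numeric matrix or data frame (subjects by
#'   sessions, k >= 2).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `icc`, `lower`, `upper`, `n`, `k`.
#' @examples
#' m <- cbind(t1 = c(10, 12, 19, 25, 31), t2 = c(11, 14, 18, 26, 30))
#' apa_icc(m)
#' @export
apa_icc <- function(measurements, conf_level = 0.95) {
  m <- as.matrix(measurements)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5 || k < 2) {
    stop("need at least 5 complete subjects and 2 sessions", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((m - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 || (ss_rows + ss_cols + ss_err) == 0) {
    stop("no between-subject variance: ICC undefined", call. = FALSE)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  tibble::tibble(icc = icc, lower = lower, upper = upper, n = n, k = k)
}

#' Independent-samples t-test (pooled variance)
#'
#' Two-sided Student t-test with pooled variance, the form used for simple
#' group contrasts (sex, race/ethnicity) on the bias score.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
apa_ttest <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(c(group_a - mean(group_a), group_b - mean(group_b))) == 0) {
    stop("zero pooled variance: t-test undefined", call. = FALSE)
  }
  fit <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(t = unname(fit$statistic), df = unname(fit$parameter),
                 p = fit$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b))
}
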