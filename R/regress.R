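# Variance-weighted regression and correlation machinery for the
# rate-versus-factor analyses: weighted least squares with
# reciprocal-variance weights, standardized multiple regression, slope
# comparison between groups, and randomization P values.

.regression_result <- function(fit, x, y, w) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  cw <- stats::cov.wt(cbind(x = x, y = y), wt = w / sum(w), cor = TRUE)
  structure(list(
    slope = co["x", "Estimate"], slope_se = co["x", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    r = cw$cor["x", "y"],
    r_model = sign(co["x", "Estimate"]) * sqrt(sm$r.squared),
    p_value = co["x", "Pr(>|t|)"],
    n = length(x), weights = w, fit = fit),
    class = "regression_result")
}

#' Variance-weighted linear regression
#'
#' Weighted least squares with weights equal to the reciprocal of each
#' point's variance (typically the gene-bootstrap variance of a rate
#' estimate). The P value is the two-sided t test of the slope; the
#' correlation `r` is the weighted Pearson correlation computed with
#' the same weights (the weighted model-R is also reported as
#' `r_model`).
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @param variances positive variances of the `y` estimates.
#' @return Object of class `regression_result`.
#' @export
weighted_linear_fit <- function(x, y, variances) {
  if (length(x) != length(y) || length(x) != length(variances))
    .stopf("x, y and variances must have equal length")
  if (length(x) < 3L) .stopf("at least 3 points are required")
  if (any(!is.finite(variances)) || any(variances <= 0))
    .stopf("variances must be positive and finite")
  w <- 1 / variances
  d <- data.frame(x = x, y = y, w = w)
  fit <- stats::lm(y ~ x, data = d, weights = w)
  .regression_result(fit, x, y, w)
}

#' Ordinary (unweighted) linear regression
#'
#' Plain least squares, used for the log-mean-|S| diagnostics where no
#' variance weights apply. Equivalent to [weighted_linear_fit()] with
#' unit variances.
#'
#' @inheritParams weighted_linear_fit
#' @export
unweighted_fit <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 3L) .stopf("at least 3 points are required")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  .regression_result(fit, x, y, rep(1, length(x)))
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression: slope = %.4g (SE %.3g), r = %.3f, P = %.3g%s, n = %d>\n",
    x$slope, x$slope_se, x$r, x$p_value,
    significance_code(x$p_value), x$n))
  invisible(x)
}

#' Standardized weighted multiple regression with two predictors
#'
#' Predictors and response are z-scored using weighted moments, then a
#' weighted least-squares fit gives unit-free standardized coefficients
#' `b_s`, so the relative influence of, say, volume and polarity
#' differences can be compared directly.
#'
#' @param X numeric matrix or data frame with two predictor columns.
#' @param y response vector.
#' @param variances positive variances of `y` (weights are their
#'   reciprocals); defaults to unit variances.
#' @return Data frame with one row per predictor: `b_s`, `se`,
#'   `p_value`.
#' @export
standardized_multiple_fit <- function(X, y, variances = rep(1, length(y))) {
  X <- as.matrix(X)
  if (ncol(X) != 2L) .stopf("X must have exactly two predictor columns")
  if (nrow(X) != length(y) || length(y) != length(variances))
    .stopf("X, y and variances must conform")
  if (any(variances <= 0)) .stopf("variances must be positive")
  if (abs(stats::cor(X[, 1], X[, 2])) > 1 - 1e-10)
    .stopf("predictors are collinear")
  w <- 1 / variances
  wz <- function(v) {
    m <- stats::weighted.mean(v, w)
    s <- sqrt(sum(w * (v - m)^2) / sum(w))
    if (s == 0) .stopf("a variable has zero weighted variance")
    (v - m) / s
  }
  d <- data.frame(y = wz(y), x1 = wz(X[, 1]), x2 = wz(X[, 2]))
  fit <- stats::lm(y ~ x1 + x2, data = d, weights = w)
  co <- stats::coef(summary(fit))
  out <- data.frame(
    predictor = colnames(X) %||% c("x1", "x2"),
    b_s = co[c("x1", "x2"), "Estimate"],
    se = co[c("x1", "x2"), "Std. Error"],
    p_value = co[c("x1", "x2"), "Pr(>|t|)"],
    row.names = NULL)
  out$predictor <- colnames(X) %||% c("x1", "x2")
  out
}

#' Compare regression slopes between two groups
#'
#' Fits a pooled weighted model with a group indicator and a
#' group-by-x interaction; the significance of the slope difference is
#' the analysis-of-variance P of the interaction term. With
#' `rescale_by_mean`, each group's response is first divided by its
#' (weighted) mean, which puts rates with very different magnitudes -
#' such as omega_na versus omega_a - on a common scale before their
#' slopes are compared.
#'
#' @param group1,group2 lists with components `x`, `y` and `variances`.
#' @param rescale_by_mean divide each group's `y` by its mean first.
#' @param weighted_mean use the weighted (default) or plain mean when
#'   rescaling.
#' @return Object of class `slope_comparison` with per-group slopes and
#'   SEs and the interaction P value.
#' @export
compare_slopes <- function(group1, group2, rescale_by_mean = FALSE,
                           weighted_mean = TRUE) {
  prep <- function(g, label) {
    if (!all(c("x", "y", "variances") %in% names(g)))
      .stopf("each group needs x, y and variances")
    if (length(g$x) < 3L) .stopf("group '%s' is degenerate (< 3 points)",
                                 label)
    w <- 1 / g$variances
    y <- g$y
    if (rescale_by_mean) {
      m <- if (weighted_mean) stats::weighted.mean(y, w) else mean(y)
      if (m == 0) .stopf("group '%s' has zero mean response", label)
      y <- y / m
      w <- w * m^2  # variances scale with the response
    }
    data.frame(x = g$x, y = y, w = w, group = label)
  }
  d <- rbind(prep(group1, "g1"), prep(group2, "g2"))
  fit <- stats::lm(y ~ x * group, data = d, weights = w)
  av <- stats::anova(fit)
  p_int <- av["x:group", "Pr(>F)"]
  fits <- lapply(split(d, d$group), function(di)
    stats::lm(y ~ x, data = di, weights = di$w))
  slopes <- vapply(fits, function(f) stats::coef(f)[["x"]], numeric(1))
  ses <- vapply(fits, function(f)
    stats::coef(summary(f))["x", "Std. Error"], numeric(1))
  structure(list(slopes = slopes, ses = ses, p_difference = p_int,
                 rescaled = rescale_by_mean),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "<slope comparison%s: %.4g (SE %.3g) vs %.4g (SE %.3g), P(diff) = %.3g>\n",
    if (x$rescaled) " (rescaled)" else "",
    x$slopes[1], x$ses[1], x$slopes[2], x$ses[2], x$p_difference))
  invisible(x)
}

#' Empirical P value from a randomization test
#'
#' One-sided on the magnitude of the statistic, with add-one smoothing
#' so the P value can never be exactly zero under a finite number of
#' permutations: `(1 + #{|permuted| >= |observed|}) / (1 + R)`.
#'
#' @param observed observed statistic.
#' @param permuted vector of statistics from permuted data sets.
#' @export
randomization_pvalue <- function(observed, permuted) {
  if (!length(permuted)) .stopf("at least one permuted value is required")
  (1 + sum(abs(permuted) >= abs(observed))) / (1 + length(permuted))
}

#' Significance codes used in the result tables
#'
#' @param p numeric vector of P values.
#' @return `"***"`, `"**"`, `"*"`, `"."` (0.05 <= P < 0.10) or `""`.
#' @export
significance_code <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else if (pi < 0.10) "." else ""
  }, character(1))
}
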