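# Univariate calibration: the direct UV-VIS method (absorbance at 540 nm
# vs Hb) and the RGB-univariate method (Redbance of the red channel vs Hb).
# Ordinary least squares in closed form, inverse prediction, ANOVA
# linearity check and 95 % confidence intervals.

#' Redbance: pseudo-absorbance of the red channel
#'
#' `Redbance = -log10(R / 256)`, where R is the red-channel mean and 256 the
#' number of RGB channels. The divisor is kept at 256 even though the
#' channel maximum is 255; values are clamped to `[1, 255]` before the
#' transform (the darkest representable red, R = 1, maps to 2.408), and
#' R = 256 is accepted only as the colourless identity giving exactly 0.
#'
#' @param r_value Red-channel means; must be positive before clamping.
#' @return Redbance units, decreasing in `r_value`.
#' @examples
#' redbance(25.6)  # 1
#' redbance(1)     # 2.408...
#' @export
redbance <- function(r_value) {
  if (any(r_value <= 0))
    stop("red channel values must be positive")
  r <- pmin(pmax(r_value, 1), 256)
  -log10(r / 256)
}

#' Univariate least-squares calibration line
#'
#' Closed-form OLS of a signal on Hb concentration, reporting the
#' intercept and slope with standard errors, 95 % confidence half-widths
#' (Student t, n - 2 df), the Pearson correlation, the residual SD and the
#' 2 x 2 normal-equations matrix `X'X` (retained for the joint elliptical
#' confidence-region test).
#'
#' @param x Predictor (Hb, g/L).
#' @param y Signal (absorbance, Redbance, or predicted Hb for
#'   method-comparison lines).
#' @return An object of class `linear_fit`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 points are required")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("degenerate design: x has zero variance")
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  s2 <- rss / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  se_intercept <- sqrt(s2 * (1 / n + xbar^2 / sxx))
  tq <- stats::qt(0.975, n - 2)
  syy <- sum((y - ybar)^2)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  structure(list(
    intercept = intercept, slope = slope,
    se_intercept = se_intercept, se_slope = se_slope,
    ci_half_intercept = tq * se_intercept, ci_half_slope = tq * se_slope,
    r = r, n = n, residual_sd = sqrt(s2),
    xtx = matrix(c(n, sum(x), sum(x), sum(x^2)), 2, 2)
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, digits = 4, ...) {
  cat(sprintf("y = (%.*f +/- %.*f) + (%.*f +/- %.*f) x   r = %.4f, n = %d\n",
              digits, x$intercept, digits, x$ci_half_intercept,
              digits, x$slope, digits, x$ci_half_slope, x$r, x$n))
  invisible(x)
}

#' Inverse prediction of Hb from a calibration line
#'
#' `(signal - intercept) / slope`. Sub-blank signals yield negative values,
#' which are reported as-is: truncation would bias the blank SD on which
#' the detection limit rests.
#'
#' @param fit A [ols_fit()] result.
#' @param signal Signal values (vectorized).
#' @return Predicted Hb (g/L).
#' @export
predict_hb <- function(fit, signal) {
  stopifnot(inherits(fit, "linear_fit"))
  if (fit$slope == 0) stop("cannot invert a zero-slope calibration")
  (signal - fit$intercept) / fit$slope
}

#' ANOVA check of calibration linearity
#'
#' Regression F statistic `F = (r^2 / (1 - r^2)) (n - 2)` on (1, n - 2)
#' degrees of freedom with its p-value. A numerically perfect fit is
#' reported with `p = 0` and `perfect_fit = TRUE`.
#'
#' @param fit A [ols_fit()] result.
#' @return List with `F`, `p`, `df` and `perfect_fit`.
#' @export
anova_linearity <- function(fit) {
  stopifnot(inherits(fit, "linear_fit"))
  r2 <- fit$r^2
  df2 <- fit$n - 2
  if (1 - r2 < 1e-12)
    return(list(F = Inf, p = 0, df = c(1, df2), perfect_fit = TRUE))
  Fstat <- r2 / (1 - r2) * df2
  list(F = Fstat, p = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
       df = c(1, df2), perfect_fit = FALSE)
}

#' Symmetric confidence interval from an estimate and half-width
#'
#' @param estimate Point estimate.
#' @param half_width Non-negative half-width (e.g. `ci_half_slope`).
#' @return `c(lower, upper)`.
#' @examples
#' confidence_interval(0.0816, 0.1257)  # -0.0441, 0.2073
#' @export
confidence_interval <- function(estimate, half_width) {
  if (any(half_width < 0)) stop("half_width must be >= 0")
  c(estimate - half_width, estimate + half_width)
}

#' Serialize / deserialize a calibration line as delimited text
#'
#' One-row CSV with every `linear_fit` field (the normal-equations matrix
#' flattened to `xtx_11, xtx_12, xtx_22`).
#'
#' @param fit A [ols_fit()] result.
#' @param path CSV path.
#' @return `write_linear_fit` returns `path` invisibly; `read_linear_fit`
#'   the restored `linear_fit`.
#' @export
write_linear_fit <- function(fit, path) {
  stopifnot(inherits(fit, "linear_fit"))
  df <- data.frame(intercept = fit$intercept, slope = fit$slope,
                   se_intercept = fit$se_intercept, se_slope = fit$se_slope,
                   ci_half_intercept = fit$ci_half_intercept,
                   ci_half_slope = fit$ci_half_slope,
                   r = fit$r, n = fit$n, residual_sd = fit$residual_sd,
                   xtx_11 = fit$xtx[1, 1], xtx_12 = fit$xtx[1, 2],
                   xtx_22 = fit$xtx[2, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_linear_fit
#' @export
read_linear_fit <- function(path) {
  df <- utils::read.csv(path)
  structure(list(
    intercept = df$intercept, slope = df$slope,
    se_intercept = df$se_intercept, se_slope = df$se_slope,
    ci_half_intercept = df$ci_half_intercept,
    ci_half_slope = df$ci_half_slope,
    r = df$r, n = df$n, residual_sd = df$residual_sd,
    xtx = matrix(c(df$xtx_11, df$xtx_12, df$xtx_12, df$xtx_22), 2, 2)
  ), class = "linear_fit")
}
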