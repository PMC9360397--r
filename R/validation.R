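# Sample splitting, animal-wise tenfold nested cross-validation, and the
# method-comparison statistics: paired t test, line-of-equality regression
# and the elliptical joint confidence region (EJCR) for (intercept, slope).

#' Stratified calibration/validation split
#'
#' Random split stratified by haemolysis level: within each level,
#' `round(fraction * n_level)` samples go to the calibration subset, so the
#' per-level proportions stay within one sample of the target. On the
#' 70-sample study design with `fraction = 0.7` this reproduces the
#' published 49/21 partition.
#'
#' @param samples Sample table with columns `sample_id` and `fraction`.
#' @param fraction Calibration share in (0, 1); default 0.70.
#' @param seed Integer seed; the plan is deterministic per seed.
#' @return An object of class `split_plan`: `calibration_ids`,
#'   `validation_ids`, `fraction`, `seed`.
#' @export
split_calibration <- function(samples, fraction = 0.7, seed = 42L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  levels_n <- table(samples$fraction)
  if (any(levels_n < 2))
    stop("every haemolysis level needs at least 2 samples; level(s) ",
         paste(names(levels_n)[levels_n < 2], collapse = ", "),
         " have fewer")
  set.seed(seed)
  cal <- unlist(lapply(split(samples$sample_id, samples$fraction),
                       function(ids) {
    n_cal <- round(fraction * length(ids))
    n_cal <- min(max(n_cal, 1), length(ids) - 1)
    sample(ids, n_cal)
  }), use.names = FALSE)
  structure(list(calibration_ids = sort(cal),
                 validation_ids = sort(setdiff(samples$sample_id, cal)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Tenfold nested cross-validation
#'
#' Folds default to the animals: with ten animals each fold is one
#' animal's seven samples, which both yields ten folds and guarantees that
#' no animal contributes to the model that predicts it. If the animal
#' count differs from `k` the function falls back, with a warning, to
#' level-stratified random folds. Each fold's model is fitted without its
#' samples ("nested": any model selection inside `fit_fn` sees only the
#' training folds) and every sample is predicted exactly once.
#'
#' @param samples Sample table with `sample_id`, `animal_id`, `fraction`
#'   and `hb_ref` columns.
#' @param fit_fn `function(train_df) -> model`.
#' @param predict_fn `function(model, test_df) -> numeric` predictions in
#'   g/L.
#' @param k Number of folds (default 10).
#' @param by_animal Use animal-wise folds when the animal count equals `k`.
#' @param seed Seed for the stratified fallback shuffle.
#' @return An object of class `cv_result`: `fold_assignments` (named
#'   integer vector, sample_id -> fold), `predictions`, `references` (both
#'   in the row order of `samples`), `per_fold_rmse`.
#' @export
nested_cv <- function(samples, fit_fn, predict_fn, k = 10,
                      by_animal = TRUE, seed = 42L) {
  n <- nrow(samples)
  animals <- unique(samples$animal_id)
  if (by_animal && length(animals) == k) {
    fold <- match(samples$animal_id, animals)
  } else {
    if (by_animal)
      warning("animal count (", length(animals), ") differs from k = ", k,
              "; falling back to stratified random folds")
    set.seed(seed)
    fold <- integer(n)
    offset <- 0L   # rotate fold labels across levels so sizes differ by <= 1
    for (ids in split(seq_len(n), samples$fraction)) {
      fold[sample(ids)] <- (offset + seq_along(ids) - 1L) %% k + 1L
      offset <- offset + length(ids)
    }
  }
  pred <- numeric(n)
  per_fold_rmse <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    te <- fold == f
    if (!any(te)) next
    model <- fit_fn(samples[!te, , drop = FALSE])
    pred[te] <- predict_fn(model, samples[te, , drop = FALSE])
    per_fold_rmse[f] <- sqrt(mean((pred[te] - samples$hb_ref[te])^2))
  }
  structure(list(
    fold_assignments = stats::setNames(fold, samples$sample_id),
    predictions = stats::setNames(pred, samples$sample_id),
    references = stats::setNames(samples$hb_ref, samples$sample_id),
    per_fold_rmse = per_fold_rmse
  ), class = "cv_result")
}

#' Paired t test between a method and the reference
#'
#' For paired differences `d = predicted - reference`:
#' `t_cal = mean(d) * sqrt(n) / sd(d)`, compared against the two-sided
#' Student t critical value at 95 % with n - 1 df. A zero difference SD
#' yields `t_cal = 0` when the mean is also zero and an infinite statistic
#' otherwise.
#'
#' @param predicted,reference Equal-length vectors (g/L), n >= 2.
#' @return An object of class `paired_t`: `mean_diff`, `sd_diff`, `n`,
#'   `t_cal`, `t_crit`, `p`, `comparable` (TRUE when `|t_cal| < t_crit`).
#' @export
paired_t <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  d <- predicted - reference
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  m <- mean(d); s <- stats::sd(d)
  t_cal <- if (s == 0) { if (m == 0) 0 else Inf * sign(m) }
           else m * sqrt(n) / s
  t_crit <- stats::qt(0.975, n - 1)
  p <- if (is.finite(t_cal)) 2 * stats::pt(abs(t_cal), n - 1,
                                           lower.tail = FALSE) else 0
  structure(list(mean_diff = m, sd_diff = s, n = n, t_cal = t_cal,
                 t_crit = t_crit, p = p,
                 comparable = abs(t_cal) < t_crit),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf(
    "Paired t: mean diff %.4f, SD %.4f, n %d -> t = %.3f (crit %.3f): %s\n",
    x$mean_diff, x$sd_diff, x$n, x$t_cal, x$t_crit,
    if (x$comparable) "methods comparable" else "methods differ"))
  invisible(x)
}

#' Line-of-equality regression
#'
#' OLS of the test method's predictions (vertical axis) on the reference
#' values (horizontal axis); agreement with the reference means the line
#' is statistically indistinguishable from slope 1, intercept 0.
#'
#' @param predicted,reference Vectors in g/L, n >= 3.
#' @return A `linear_fit` (see [ols_fit()]).
#' @export
equality_line <- function(predicted, reference) {
  ols_fit(reference, predicted)
}

#' Elliptical joint confidence region test for (intercept, slope)
#'
#' The fitted pair `b = (intercept, slope)` is compatible with the target
#' `beta = (beta0, beta1)` at level `1 - alpha` iff
#' `(b - beta)' X'X (b - beta) <= 2 s^2 F(1 - alpha; 2, n - 2)`,
#' where `X'X` is the normal-equations matrix retained in the fit and
#' `s^2` the residual mean square. The region is an ellipse in the
#' (intercept, slope) plane; a method agrees with the reference when
#' (0, 1) lies inside.
#'
#' @param fit A `linear_fit` from [equality_line()] / [ols_fit()].
#' @param beta0,beta1 Target intercept and slope (defaults 0 and 1).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `ejcr`: `inside`, `statistic`, `critical`,
#'   `alpha`.
#' @export
ejcr_test <- function(fit, beta0 = 0, beta1 = 1, alpha = 0.05) {
  stopifnot(inherits(fit, "linear_fit"))
  if (fit$n <= 2) stop("EJCR needs n > 2")
  db <- c(fit$intercept - beta0, fit$slope - beta1)
  statistic <- drop(t(db) %*% fit$xtx %*% db)
  critical <- 2 * fit$residual_sd^2 * stats::qf(1 - alpha, 2, fit$n - 2)
  structure(list(inside = statistic <= critical, statistic = statistic,
                 critical = critical, alpha = alpha),
            class = "ejcr")
}

#' @export
print.ejcr <- function(x, ...) {
  cat(sprintf(
    "EJCR at %d%%: statistic %.4g vs critical %.4g -> (0,1) %s the region\n",
    round(100 * (1 - x$alpha)), x$statistic, x$critical,
    if (x$inside) "inside" else "outside"))
  invisible(x)
}

#' Full method-comparison report
#'
#' Bundles the line-of-equality regression with its 95 % confidence
#' intervals, the paired t test and the EJCR test into one object.
#'
#' @param predicted,reference Vectors in g/L.
#' @param method Label of the test method.
#' @param alpha Significance level.
#' @return An object of class `comparison_report`.
#' @export
comparison_report <- function(predicted, reference, method = "method",
                              alpha = 0.05) {
  fit <- equality_line(predicted, reference)
  structure(list(
    method = method,
    equality_fit = fit,
    intercept_ci = confidence_interval(fit$intercept, fit$ci_half_intercept),
    slope_ci = confidence_interval(fit$slope, fit$ci_half_slope),
    paired = paired_t(predicted, reference),
    ejcr = ejcr_test(fit, alpha = alpha),
    alpha = alpha
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Method comparison: %s vs reference (n = %d)\n",
              x$method, x$equality_fit$n))
  cat("  equality line: "); print(x$equality_fit)
  cat(sprintf("  95%% CI intercept (%.4f, %.4f), slope (%.4f, %.4f)\n",
              x$intercept_ci[1], x$intercept_ci[2],
              x$slope_ci[1], x$slope_ci[2]))
  cat("  "); print(x$paired)
  cat("  "); print(x$ejcr)
  invisible(x)
}

#' Serialize a comparison report as one CSV row
#'
#' @param report A [comparison_report()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  f <- report$equality_fit
  df <- data.frame(
    method = report$method, n = f$n,
    intercept = f$intercept, slope = f$slope, r = f$r,
    intercept_lo = report$intercept_ci[1],
    intercept_hi = report$intercept_ci[2],
    slope_lo = report$slope_ci[1], slope_hi = report$slope_ci[2],
    mean_diff = report$paired$mean_diff, sd_diff = report$paired$sd_diff,
    t_cal = report$paired$t_cal, t_crit = report$paired$t_crit,
    ejcr_inside = report$ejcr$inside,
    ejcr_statistic = report$ejcr$statistic,
    ejcr_critical = report$ejcr$critical
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
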