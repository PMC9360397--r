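# Multivariate calibration of Hb from (R, G, B, intensity) by NIPALS
# partial least squares regression on autoscaled predictors.

#' Fit a PLS regression model by NIPALS
#'
#' Predictors are autoscaled (z-scores) and the response centred and
#' scaled internally. Latent factors are extracted one at a time by NIPALS
#' with deflation of both `X` and `y` after each factor; cumulative
#' explained X- and Y-variance percentages are recorded per factor count.
#' If the predictor matrix runs out of rank before `n_lf` factors the
#' extraction stops early with a warning and the model records the actual
#' factor count.
#'
#' @param X Numeric matrix, samples x predictors (no missing values).
#' @param y Response vector (Hb, g/L).
#' @param n_lf Number of latent factors, `1 <= n_lf <= ncol(X)`.
#' @return An object of class `pls_model` with weights, loadings, scores,
#'   scaling parameters, regression coefficients on the raw scale and the
#'   explained-variance traces.
#' @export
pls_fit <- function(X, y, n_lf) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (n_lf < 1 || n_lf > p)
    stop("n_lf must lie between 1 and the number of predictors (", p, ")")
  if (n < n_lf + 2) stop("need at least n_lf + 2 samples")
  x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd == 0)) {
    nm <- colnames(X)[x_sd == 0]
    if (is.null(nm)) nm <- which(x_sd == 0)
    stop("zero-variance predictor: ", paste(nm, collapse = ", "))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) y_sd <- 1
  X0 <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y0 <- (y - y_mean) / y_sd
  tss_x <- sum(X0^2); tss_y <- sum(y0^2)

  W <- P <- matrix(0, p, n_lf)
  Tm <- matrix(0, n, n_lf)
  Q <- numeric(n_lf)
  exp_x <- exp_y <- numeric(n_lf)
  a_actual <- 0
  for (a in seq_len(n_lf)) {
    w <- drop(crossprod(X0, y0))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) {
      warning("predictor matrix rank exhausted after ", a_actual,
              " latent factors (", n_lf, " requested)")
      break
    }
    w <- w / nw
    t_a <- drop(X0 %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(X0, t_a)) / tt
    q_a <- sum(y0 * t_a) / tt
    X0 <- X0 - tcrossprod(t_a, p_a)
    y0 <- y0 - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; Q[a] <- q_a
    exp_x[a] <- 100 * (1 - sum(X0^2) / tss_x)
    exp_y[a] <- 100 * (1 - sum(y0^2) / max(tss_y, .Machine$double.eps))
    a_actual <- a
  }
  if (a_actual == 0) stop("no latent factor could be extracted")
  W <- W[, 1:a_actual, drop = FALSE]; P <- P[, 1:a_actual, drop = FALSE]
  Tm <- Tm[, 1:a_actual, drop = FALSE]; Q <- Q[1:a_actual]
  b_scaled <- drop(W %*% solve(crossprod(P, W), Q))
  coefficients <- y_sd * b_scaled / x_sd
  intercept <- y_mean - sum(coefficients * x_mean)
  structure(list(
    n_lf = a_actual, n_lf_requested = n_lf,
    x_weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
    x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
    coefficients = coefficients, intercept = intercept,
    explained_x_variance = exp_x[1:a_actual],
    explained_y_variance = exp_y[1:a_actual],
    n_predictors = p
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d latent factor(s), %d predictors\n",
              x$n_lf, x$n_predictors))
  cat(sprintf("  cumulative explained variance: X %s%%, Y %s%%\n",
              paste(sprintf("%.1f", x$explained_x_variance), collapse = "/"),
              paste(sprintf("%.1f", x$explained_y_variance), collapse = "/")))
  invisible(x)
}

#' Predict Hb from a PLS model
#'
#' @param model A [pls_fit()] result.
#' @param X New predictor matrix with the same number of columns as the
#'   training matrix.
#' @return Predicted Hb (g/L).
#' @export
pls_predict <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_predictors)
    stop("X has ", ncol(X), " columns; model expects ", model$n_predictors)
  drop(X %*% model$coefficients) + model$intercept
}

#' Select the latent-factor count by cross-validated RMSE
#'
#' k-fold cross-validation of [pls_fit()] at each factor count up to
#' `max_lf`; the chosen rank is the smallest whose CV-RMSE lies within
#' `tol` (default 5 %) of the global minimum — a one-standard-rule variant
#' favouring parsimony. If even the best factor count predicts no better
#' than the response SD, a warning flags the response as noise-like.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param max_lf Largest factor count to try (<= `ncol(X)`).
#' @param k Folds (reduced to `nrow(X)` if larger).
#' @param seed Seed for the fold shuffle.
#' @param tol Relative tolerance above the minimum CV-RMSE.
#' @return The selected factor count (integer) with attribute `rmsecv`
#'   (the per-rank CV-RMSE vector) and attribute `noise_flag`.
#' @export
select_n_lf <- function(X, y, max_lf = 4, k = 10, seed = 42L, tol = 0.05) {
  X <- as.matrix(X)
  if (max_lf > ncol(X)) stop("max_lf cannot exceed the number of predictors")
  n <- nrow(X)
  k <- min(k, n)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  rmse <- numeric(max_lf)
  for (a in seq_len(max_lf)) {
    pred <- numeric(n)
    for (f in seq_len(k)) {
      te <- fold == f
      m <- suppressWarnings(pls_fit(X[!te, , drop = FALSE], y[!te], a))
      pred[te] <- pls_predict(m, X[te, , drop = FALSE])
    }
    rmse[a] <- sqrt(mean((pred - y)^2))
  }
  chosen <- which(rmse <= (1 + tol) * min(rmse))[1]
  noise <- min(rmse) >= stats::sd(y)
  if (noise)
    warning("response looks like noise: best CV-RMSE (",
            signif(min(rmse), 3), ") is no better than sd(y)")
  structure(as.integer(chosen), rmsecv = rmse, noise_flag = noise)
}
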