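# Multilayer feed-forward neural network (4-7-1) for Hb calibration,
# trained from scratch by batch backpropagation with momentum.
#
# Conventions: sigmoid activation in every layer including the output;
# inputs min-max scaled to [0, 1] per predictor; the Hb target min-max
# mapped to [0.1, 0.9] (a sigmoid output cannot reach 0 or 1); batch
# updates on the summed squared error E = 1/2 * sum (o - y)^2, so the
# step size of the published learning rate is appropriate at the study's
# sample scale (n ~ 50-70); bias units in every layer, initialized like
# the connection weights.

#' Numerically plain logistic sigmoid
#'
#' `f(x) = 1 / (1 + exp(-x))`; monotone, stable over at least
#' `|x| <= 700` (beyond that it saturates cleanly to 0 or 1).
#'
#' @param x Numeric.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Hyperparameter specification of the feed-forward network
#'
#' Defaults are the published training recipe: a 4-7-1 architecture,
#' sigmoidal transfer, learning rate 0.2, momentum 0.5, at most 500 epochs,
#' and initial weights drawn uniformly from `[-3, 3]`.
#'
#' @param layer_sizes Integer vector (input, hidden..., output).
#' @param eta Learning rate (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param max_epochs Epoch cap (>= 1).
#' @param init_range Half-width of the uniform weight initialization.
#' @param seed Integer seed for the initialization.
#' @return An object of class `ann_spec`.
#' @export
ann_spec <- function(layer_sizes = c(4, 7, 1), eta = 0.2, momentum = 0.5,
                     max_epochs = 500L, init_range = 3, seed = 42L) {
  if (any(layer_sizes < 1)) stop("layer sizes must be positive")
  if (eta <= 0) stop("eta must be > 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(layer_sizes = as.integer(layer_sizes), eta = eta,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 init_range = init_range, seed = as.integer(seed)),
            class = "ann_spec")
}

#' Initialize network weights
#'
#' All connection weights and biases are drawn uniformly from
#' `[-init_range, init_range]`, deterministically for a given seed. For the
#' default 4-7-1 architecture that is 7x4 + 7 + 1x7 + 1 = 43 parameters.
#'
#' @param spec An [ann_spec()].
#' @return An untrained object of class `ann_model`.
#' @export
ann_init <- function(spec = ann_spec()) {
  stopifnot(inherits(spec, "ann_spec"))
  set.seed(spec$seed)
  L <- length(spec$layer_sizes) - 1
  weights <- biases <- vector("list", L)
  for (l in seq_len(L)) {
    n_out <- spec$layer_sizes[l + 1]; n_in <- spec$layer_sizes[l]
    weights[[l]] <- matrix(stats::runif(n_out * n_in, -spec$init_range,
                                        spec$init_range), n_out, n_in)
    biases[[l]] <- stats::runif(n_out, -spec$init_range, spec$init_range)
  }
  structure(list(spec = spec, weights = weights, biases = biases,
                 trained = FALSE, x_min = NULL, x_range = NULL,
                 y_min = NULL, y_range = NULL,
                 training_rmse_trace = numeric(0)),
            class = "ann_model")
}

#' Number of free parameters of a network
#' @param model An `ann_model`.
#' @return Integer parameter count.
#' @export
ann_n_params <- function(model) {
  sum(vapply(model$weights, length, 1L)) +
    sum(vapply(model$biases, length, 1L))
}

# forward pass on the scaled input matrix; returns activations per layer
ann_forward <- function(model, Xs) {
  acts <- list(Xs)
  for (l in seq_along(model$weights)) {
    z <- acts[[l]] %*% t(model$weights[[l]]) +
      matrix(model$biases[[l]], nrow(Xs), length(model$biases[[l]]),
             byrow = TRUE)
    acts[[l + 1]] <- sigmoid(z)
  }
  acts
}

# analytic batch gradients of E = 1/2 sum (o - y)^2 w.r.t. all weights and
# biases; used by ann_train and by the numerical gradient check in tests
ann_gradients <- function(model, Xs, ys) {
  L <- length(model$weights)
  acts <- ann_forward(model, Xs)
  out <- acts[[L + 1]]
  delta <- (out - ys) * out * (1 - out)          # n x n_out
  gw <- gb <- vector("list", L)
  for (l in L:1) {
    gw[[l]] <- t(delta) %*% acts[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      a <- acts[[l]]
      delta <- (delta %*% model$weights[[l]]) * a * (1 - a)
    }
  }
  list(weights = gw, biases = gb,
       loss = 0.5 * sum((out - ys)^2),
       rmse = sqrt(mean((out - ys)^2)))
}

#' Train the network by batch backpropagation with momentum
#'
#' Inputs are min-max scaled to `[0, 1]` per predictor and the target
#' min-max mapped to `[0.1, 0.9]`, both fitted on the training data and
#' stored in the model. One epoch is one batch update on the summed
#' squared error with momentum
#' `v <- momentum * v - eta * gradient; w <- w + v`. Training stops at
#' `max_epochs` or as soon as the epoch-to-epoch change in training RMSE
#' falls below 1e-7 (the absolute change, so transient oscillation of the
#' momentum dynamics does not trigger a premature stop); the per-epoch
#' RMSE trace (on the scaled target) is recorded.
#'
#' @param model An [ann_init()] result.
#' @param X Training predictor matrix (raw scale).
#' @param y Training response (Hb, g/L).
#' @return The trained `ann_model`.
#' @export
ann_train <- function(model, X, y) {
  stopifnot(inherits(model, "ann_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$spec$layer_sizes[1])
    stop("X has ", ncol(X), " columns; network expects ",
         model$spec$layer_sizes[1])
  model$x_min <- apply(X, 2, min)
  model$x_range <- apply(X, 2, max) - model$x_min
  model$x_range[model$x_range == 0] <- 1
  model$y_min <- min(y)
  model$y_range <- max(y) - model$y_min
  if (model$y_range == 0) model$y_range <- 1
  Xs <- sweep(sweep(X, 2, model$x_min), 2, model$x_range, "/")
  ys <- matrix(0.1 + 0.8 * (y - model$y_min) / model$y_range, ncol = 1)

  vW <- lapply(model$weights, function(w) w * 0)
  vb <- lapply(model$biases, function(b) b * 0)
  eta <- model$spec$eta; mom <- model$spec$momentum
  trace <- numeric(model$spec$max_epochs)
  prev_rmse <- Inf
  n_epochs <- 0
  for (e in seq_len(model$spec$max_epochs)) {
    g <- ann_gradients(model, Xs, ys)
    if (!is.finite(g$loss))
      stop("training aborted: non-finite loss at epoch ", e)
    trace[e] <- g$rmse
    n_epochs <- e
    for (l in seq_along(model$weights)) {
      vW[[l]] <- mom * vW[[l]] - eta * g$weights[[l]]
      vb[[l]] <- mom * vb[[l]] - eta * g$biases[[l]]
      model$weights[[l]] <- model$weights[[l]] + vW[[l]]
      model$biases[[l]] <- model$biases[[l]] + vb[[l]]
    }
    if (abs(prev_rmse - g$rmse) < 1e-7) break
    prev_rmse <- g$rmse
  }
  model$training_rmse_trace <- trace[seq_len(n_epochs)]
  model$trained <- TRUE
  model
}

#' Predict Hb with a trained network
#'
#' Forward pass on min-max-scaled inputs followed by the inverse target
#' scaling back to g/L.
#'
#' @param model A trained [ann_train()] model.
#' @param X Predictor matrix (raw scale).
#' @return Predicted Hb (g/L).
#' @export
ann_predict <- function(model, X) {
  stopifnot(inherits(model, "ann_model"))
  if (!model$trained) stop("model has not been trained")
  X <- as.matrix(X)
  if (ncol(X) != model$spec$layer_sizes[1])
    stop("X has ", ncol(X), " columns; network expects ",
         model$spec$layer_sizes[1])
  Xs <- sweep(sweep(X, 2, model$x_min), 2, model$x_range, "/")
  out <- ann_forward(model, Xs)[[length(model$weights) + 1]]
  model$y_min + (drop(out) - 0.1) / 0.8 * model$y_range
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("Feed-forward network %s, %d parameters, %s\n",
              paste(x$spec$layer_sizes, collapse = "-"), ann_n_params(x),
              if (x$trained)
                sprintf("trained (%d epochs, final RMSE %.4g)",
                        length(x$training_rmse_trace),
                        utils::tail(x$training_rmse_trace, 1))
              else "untrained"))
  invisible(x)
}

#' Serialize / deserialize network models as JSON
#'
#' Plain-text JSON carrying the spec, the flattened weight and bias lists
#' with their shapes, the scaling parameters and the training trace.
#'
#' @param model An `ann_model`.
#' @param path JSON file path.
#' @return `write_ann_model` returns `path` invisibly; `read_ann_model`
#'   the restored model.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  obj <- list(
    spec = unclass(model$spec),
    weights = lapply(model$weights, function(w)
      list(dim = dim(w), values = as.vector(w))),
    biases = model$biases,
    trained = model$trained,
    x_min = model$x_min, x_range = model$x_range,
    y_min = model$y_min, y_range = model$y_range,
    training_rmse_trace = model$training_rmse_trace
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- do.call(ann_spec, lapply(obj$spec, function(v) unlist(v)))
  weights <- lapply(obj$weights, function(w)
    matrix(unlist(w$values), unlist(w$dim)[1], unlist(w$dim)[2]))
  structure(list(spec = spec,
                 weights = weights,
                 biases = lapply(obj$biases, function(b) unlist(b)),
                 trained = isTRUE(obj$trained),
                 x_min = unlist(obj$x_min), x_range = unlist(obj$x_range),
                 y_min = unlist(obj$y_min), y_range = unlist(obj$y_range),
                 training_rmse_trace =
                   if (is.null(obj$training_rmse_trace)) numeric(0)
                   else unlist(obj$training_rmse_trace)),
            class = "ann_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
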