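## Regressors from PCA-reduced brain responses to action-feature targets:
## the multi-task loss-constrained MLP plus ridge, KNN and plain-MLP
## baselines, behind one fitting function returning a classed model object.

#' Specification of a feature regressor
#'
#' Collects every tunable of the fMRI-to-feature regression in one place.
#' Defaults follow the decoding setup: a three-layer network (input
#' `k_eff`, hidden 432, output `d0`) with batch normalization, dropout 0.4,
#' SGD at learning rate 1e-4, batch size 16, 1,000 epochs, and multi-task
#' loss weights `w0 = 2.2` (action features) and `w1 = 1` (auxiliary pooled
#' features); ridge regularization `alpha = 0.2`; KNN with `k = 7`
#' neighbours, uniform weights, Euclidean (Minkowski power 2) distance.
#'
#' @param kind one of `"multitask_mlp"`, `"mlp"`, `"ridge"`, `"knn"`.
#' @param hidden_dim hidden-layer width (default 432, the auxiliary
#'   feature dimension — the auxiliary loss requires this match).
#' @param dropout dropout rate in `[0, 1)` (default 0.4).
#' @param batch_norm logical; batch-normalize the hidden layer (default TRUE).
#' @param w0,w1 nonnegative multi-task loss weights (defaults 2.2 and 1;
#'   `kind = "mlp"` forces `w1 = 0`).
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param momentum SGD momentum (default 0; the optimiser is plain SGD).
#' @param batch_size mini-batch size (default 16).
#' @param epochs fixed epoch count (default 1000).
#' @param ridge_alpha L2 penalty for `kind = "ridge"` (default 0.2).
#' @param knn_k neighbour count for `kind = "knn"` (default 7).
#' @param standardize z-score inputs using training statistics
#'   (default TRUE; applied identically at prediction time).
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @return A list of class `regressor_spec`.
#' @export
regressor_spec <- function(kind = c("multitask_mlp", "mlp", "ridge", "knn"),
                           hidden_dim = 432L, dropout = 0.4,
                           batch_norm = TRUE, w0 = 2.2, w1 = 1,
                           learning_rate = 1e-4, momentum = 0,
                           batch_size = 16L, epochs = 1000L,
                           ridge_alpha = 0.2, knn_k = 7L,
                           standardize = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "mlp") w1 <- 0
  if (w0 < 0 || w1 < 0) stop("loss weights w0, w1 must be nonnegative")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (hidden_dim < 1L || batch_size < 1L || epochs < 1L || knn_k < 1L)
    stop("dimensions and counts must be positive")
  structure(list(kind = kind, hidden_dim = as.integer(hidden_dim),
                 dropout = dropout, batch_norm = isTRUE(batch_norm),
                 w0 = w0, w1 = w1,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 ridge_alpha = ridge_alpha, knn_k = as.integer(knn_k),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Fit a regressor from reduced brain responses to feature targets
#'
#' The core fitting function of the toolkit. For the (multi-task) MLP the
#' loss is the per-sample mean of the dimension-summed squared errors,
#' `L = (1/n) (w0 * sum ||y0 - y0hat||^2 + w1 * sum ||y1 - y1hat||^2)`,
#' where the auxiliary prediction `y1hat` is the 432-dim post-ReLU hidden
#' activation; ridge and KNN fit per-output-dimension on `(X, y0)` only.
#' Inputs are z-scored with training statistics when
#' `spec$standardize` (targets are used raw).
#'
#' @param X samples x k numeric matrix of PCA scores (training fold).
#' @param y0 samples x d0 action-feature targets.
#' @param y1 samples x d1 auxiliary targets (required when `w1 > 0`).
#' @param spec a `regressor_spec`.
#' @return An object of class `feature_regressor` with `print`, `summary`,
#'   `predict`, `plot`, `coef` and `residuals` methods.
#' @export
fit_regressor <- function(X, y0, y1 = NULL, spec = regressor_spec()) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- as.matrix(X); y0 <- as.matrix(y0)
  check_finite(X, "X"); check_finite(y0, "y0")
  if (nrow(X) != nrow(y0)) stop("X and y0 must have aligned rows")
  uses_aux <- spec$kind %in% c("multitask_mlp", "mlp") && spec$w1 > 0
  if (uses_aux) {
    if (is.null(y1))
      stop("multi-task loss (w1 > 0) requires auxiliary targets y1")
    y1 <- as.matrix(y1)
    check_finite(y1, "y1")
    if (nrow(y1) != nrow(X)) stop("X and y1 must have aligned rows")
    if (spec$kind %in% c("multitask_mlp", "mlp") &&
        ncol(y1) != spec$hidden_dim)
      stop(sprintf("auxiliary target dimension %d must equal hidden_dim %d",
                   ncol(y1), spec$hidden_dim))
  }
  center <- scale_ <- NULL
  if (spec$standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale_, `/`)
    message("inputs z-scored with training-fold statistics; targets used raw")
  }

  fit <- switch(spec$kind,
    multitask_mlp = ,
    mlp = with_seed(spec$seed,
      mlp_train(X, y0, y1, hidden = spec$hidden_dim,
                lr = spec$learning_rate, momentum = spec$momentum,
                dropout = spec$dropout, batch_norm = spec$batch_norm,
                w0 = spec$w0, w1 = spec$w1,
                batch_size = spec$batch_size, epochs = spec$epochs)),
    ridge = ridge_fit(X, y0, spec$ridge_alpha),
    knn = list(X = X, y0 = y0))

  structure(list(spec = spec, fit = fit,
                 loss_trace = fit$trace,
                 center = center, scale = scale_,
                 d0 = ncol(y0), n_train = nrow(X), k_in = ncol(X)),
            class = "feature_regressor")
}

## Closed-form ridge with an unpenalised intercept: center X and Y, solve
## (X'X + alpha I) B = X'Y, recover the intercept from the means. Matches
## the usual Ridge(alpha) convention (penalty on the raw coefficients, not
## scaled by n).
ridge_fit <- function(X, Y, alpha) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  G <- crossprod(Xc)
  diag(G) <- diag(G) + alpha
  B <- solve(G, crossprod(Xc, Yc))
  list(B = B, intercept = ym - drop(xm %*% B))
}

knn_predict <- function(trainX, trainY, k, newX) {
  ## exact k-nearest-neighbour regression: Euclidean distance, uniform
  ## weights, ties resolved by training-row order
  d2 <- outer(rowSums(newX^2), rowSums(trainX^2), `+`) -
    2 * tcrossprod(newX, trainX)
  t(apply(d2, 1L, function(dr) {
    nn <- order(dr)[seq_len(min(k, length(dr)))]
    colMeans(trainY[nn, , drop = FALSE])
  }))
}

#' Predict feature targets from new reduced responses
#'
#' Deterministic at inference: dropout disabled, batch normalization in
#' running-statistics mode.
#'
#' @param object a fitted `feature_regressor`.
#' @param newdata samples x k matrix in the regressor's input space
#'   (post-PCA, pre-standardization).
#' @param type `"y0"` for the action-feature prediction (matrix), or
#'   `"both"` for a list with the auxiliary prediction too (MLP kinds only).
#' @param ... unused.
#' @return matrix of predicted `y0`, or a list `(y0_hat, y1_hat)`.
#' @export
predict.feature_regressor <- function(object, newdata, type = c("y0", "both"),
                                      ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$k_in)
    stop(sprintf("newdata has %d columns; regressor expects %d",
                 ncol(X), object$k_in))
  check_finite(X, "newdata")
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, `/`)
  spec <- object$spec
  out <- switch(spec$kind,
    multitask_mlp = ,
    mlp = mlp_predict(object$fit$par, X),
    ridge = list(y0_hat = sweep(X %*% object$fit$B, 2L,
                                object$fit$intercept, `+`),
                 y1_hat = NULL),
    knn = list(y0_hat = knn_predict(object$fit$X, object$fit$y0,
                                    spec$knn_k, X),
               y1_hat = NULL))
  if (type == "y0") out$y0_hat else out
}

#' Predicted primary and auxiliary features
#'
#' Convenience wrapper over [predict.feature_regressor()] returning both
#' heads.
#'
#' @param reg a fitted `feature_regressor`.
#' @param X samples x k input matrix.
#' @return list with `y0_hat` and `y1_hat` (`NULL` for ridge/KNN).
#' @export
predict_features <- function(reg, X) {
  predict(reg, X, type = "both")
}

#' @export
print.feature_regressor <- function(x, ...) {
  cat(sprintf("Feature regressor (%s): %d -> %d, trained on %d samples\n",
              x$spec$kind, x$k_in, x$d0, x$n_train))
  if (!is.null(x$loss_trace))
    cat(sprintf("  final training loss: %.4g (%d epochs)\n",
                x$loss_trace[length(x$loss_trace)], length(x$loss_trace)))
  invisible(x)
}

#' @export
summary.feature_regressor <- function(object, ...) {
  s <- object$spec
  cat(sprintf("Feature regressor: %s\n", s$kind))
  cat(sprintf("  input dim %d, output dim %d, %d training samples\n",
              object$k_in, object$d0, object$n_train))
  if (s$kind %in% c("multitask_mlp", "mlp")) {
    cat(sprintf("  hidden %d, dropout %.2f, batch norm %s\n",
                s$hidden_dim, s$dropout, s$batch_norm))
    cat(sprintf("  loss weights w0 = %.2f, w1 = %.2f\n", s$w0, s$w1))
    cat(sprintf("  SGD lr %.2g, momentum %.2g, batch %d, %d epochs\n",
                s$learning_rate, s$momentum, s$batch_size, s$epochs))
    tr <- object$loss_trace
    cat(sprintf("  loss: first %.4g, final %.4g\n", tr[1], tr[length(tr)]))
  } else if (s$kind == "ridge") {
    cat(sprintf("  alpha = %.3g\n", s$ridge_alpha))
  } else {
    cat(sprintf("  k = %d neighbours, uniform weights, Euclidean\n", s$knn_k))
  }
  invisible(object)
}

#' @export
plot.feature_regressor <- function(x, ...) {
  if (is.null(x$loss_trace))
    stop("no loss trace: only MLP kinds record one")
  graphics::plot(x$loss_trace, type = "l", xlab = "epoch",
                 ylab = "training loss", main = x$spec$kind, ...)
  invisible(x)
}

#' @export
coef.feature_regressor <- function(object, ...) {
  switch(object$spec$kind,
         ridge = rbind(`(intercept)` = object$fit$intercept, object$fit$B),
         multitask_mlp = ,
         mlp = object$fit$par[c("W1", "b1", "gamma", "beta", "W2", "b2")],
         knn = stop("KNN has no coefficients"))
}

#' @export
residuals.feature_regressor <- function(object, X, y0, ...) {
  y0 - predict(object, X)
}
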