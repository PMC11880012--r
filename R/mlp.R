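## Multi-task loss-constrained MLP, written as an explicit forward/backward
## engine in base R matrix algebra. The network is a three-layer fully
## connected mapping: PCA scores (nominally 1,000) -> 432 hidden units
## (affine -> batch normalization -> ReLU -> dropout) -> d0 outputs (affine
## only). The auxiliary loss term attaches to the post-ReLU, pre-dropout
## 432-dim hidden activation, whose dimension matches the auxiliary pooled
## feature target; the primary term to the final output:
##
##   L = (1/n) * ( w0 * sum_i ||y0_i - y0hat_i||^2
##               + w1 * sum_i ||y1_i - y1hat_i||^2 )
##
## (sum over feature dimensions, mean over samples). Optimised by
## mini-batch SGD with seeded shuffling and a fixed epoch count.
##
## Everything below works feature-major (features are rows, samples are
## columns) so per-feature broadcasts ride R's column recycling instead of
## sweep(); callers hand in sample-major matrices and get them back.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

mlp_init <- function(k, hidden, d0, batch_norm) {
  ## He-scaled Gaussian fan-in initialisation (caller seeds the RNG);
  ## weights stored feature-major: W1 is hidden x k, W2 is d0 x hidden
  list(W1 = matrix(rnorm(k * hidden, sd = sqrt(2 / k)), hidden, k),
       b1 = rep(0, hidden),
       gamma = rep(1, hidden), beta = rep(0, hidden),
       run_mean = rep(0, hidden), run_var = rep(1, hidden),
       W2 = matrix(rnorm(hidden * d0, sd = sqrt(2 / hidden)), d0, hidden),
       b2 = rep(0, d0),
       batch_norm = batch_norm)
}

## Forward pass on a k x B input block; returns the feature-major
## intermediates needed for the backward pass.
mlp_forward_t <- function(par, Xt, dropout = 0, training = FALSE) {
  a1 <- par$W1 %*% Xt + par$b1                    # hidden x B
  if (par$batch_norm) {
    if (training) {
      mu <- rowMeans(a1)
      v <- rowMeans((a1 - mu)^2)                  # biased batch variance
    } else {
      mu <- par$run_mean; v <- par$run_var
    }
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- (a1 - mu) * invstd
    bn <- xhat * par$gamma + par$beta
  } else {
    bn <- a1; xhat <- NULL; invstd <- NULL; mu <- NULL; v <- NULL
  }
  h <- bn * (bn > 0)                              # ReLU; the auxiliary output
  if (training && dropout > 0) {
    mask <- matrix(runif(length(h)) >= dropout, nrow(h), ncol(h))
    hd <- h * mask / (1 - dropout)
  } else {
    mask <- NULL
    hd <- h
  }
  out <- par$W2 %*% hd + par$b2                   # d0 x B
  list(xhat = xhat, invstd = invstd, batch_mu = mu, batch_var = v,
       bn = bn, h = h, mask = mask, hd = hd, out = out)
}

## Loss on feature-major blocks (targets d0 x B and hidden x B).
mlp_loss_t <- function(fw, y0t, y1t, w0, w1) {
  n <- ncol(y0t)
  l <- w0 * sum((y0t - fw$out)^2)
  if (w1 > 0) l <- l + w1 * sum((y1t - fw$h)^2)
  l / n
}

mlp_backward_t <- function(par, Xt, fw, y0t, y1t, w0, w1, dropout) {
  B <- ncol(Xt)
  d_out <- (2 * w0 / B) * (fw$out - y0t)          # d0 x B
  gW2 <- tcrossprod(d_out, fw$hd)
  gb2 <- rowSums(d_out)
  d_hd <- crossprod(par$W2, d_out)                # hidden x B
  d_h <- if (!is.null(fw$mask)) d_hd * fw$mask / (1 - dropout) else d_hd
  if (w1 > 0) d_h <- d_h + (2 * w1 / B) * (fw$h - y1t)
  d_bn <- d_h * (fw$bn > 0)
  if (par$batch_norm) {
    ggamma <- rowSums(d_bn * fw$xhat)
    gbeta <- rowSums(d_bn)
    d_xhat <- d_bn * par$gamma
    d_a1 <- (d_xhat - rowMeans(d_xhat) -
               fw$xhat * rowMeans(d_xhat * fw$xhat)) * fw$invstd
  } else {
    ggamma <- NULL; gbeta <- NULL
    d_a1 <- d_bn
  }
  gW1 <- tcrossprod(d_a1, Xt)
  gb1 <- rowSums(d_a1)
  list(W1 = gW1, b1 = gb1, gamma = ggamma, beta = gbeta, W2 = gW2, b2 = gb2)
}

## Mini-batch SGD training loop on sample-major inputs. Returns the
## parameters and the per-epoch mean loss trace. Remainder batches of a
## single sample are skipped (batch statistics are undefined there).
mlp_train <- function(X, y0, y1, hidden, lr, momentum, dropout, batch_norm,
                      w0, w1, batch_size, epochs) {
  n <- nrow(X)
  Xt <- t(X); y0t <- t(y0)
  y1t <- if (w1 > 0) t(y1) else NULL
  par <- mlp_init(ncol(X), hidden, ncol(y0), batch_norm)
  upd_names <- c("W1", "b1", if (batch_norm) c("gamma", "beta"), "W2", "b2")
  vel <- lapply(par[upd_names], function(p) p * 0)
  trace <- numeric(epochs)
  use_momentum <- momentum != 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    ep_count <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      B <- length(idx)
      if (B < 2L && batch_norm) next
      Xb <- Xt[, idx, drop = FALSE]
      y0b <- y0t[, idx, drop = FALSE]
      y1b <- if (w1 > 0) y1t[, idx, drop = FALSE] else NULL
      fw <- mlp_forward_t(par, Xb, dropout, training = TRUE)
      l <- mlp_loss_t(fw, y0b, y1b, w0, w1)
      if (!is.finite(l))
        stop(sprintf("loss became non-finite at epoch %d; lower the learning rate or target scale", ep))
      gr <- mlp_backward_t(par, Xb, fw, y0b, y1b, w0, w1, dropout)
      if (use_momentum) {
        for (nm in upd_names) {
          vel[[nm]] <- momentum * vel[[nm]] - lr * gr[[nm]]
          par[[nm]] <- par[[nm]] + vel[[nm]]
        }
      } else {
        for (nm in upd_names) par[[nm]] <- par[[nm]] - lr * gr[[nm]]
      }
      if (batch_norm) {
        unb <- fw$batch_var * B / (B - 1)
        par$run_mean <- (1 - BN_MOMENTUM) * par$run_mean + BN_MOMENTUM * fw$batch_mu
        par$run_var <- (1 - BN_MOMENTUM) * par$run_var + BN_MOMENTUM * unb
      }
      ep_loss <- ep_loss + l * B
      ep_count <- ep_count + B
    }
    trace[ep] <- ep_loss / ep_count
  }
  list(par = par, trace = trace)
}

## Sample-major prediction wrapper used by predict methods.
mlp_predict <- function(par, X) {
  fw <- mlp_forward_t(par, t(X), dropout = 0, training = FALSE)
  list(y0_hat = t(fw$out), y1_hat = t(fw$h))
}
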