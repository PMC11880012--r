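# The multi-task loss and its optimizer, plus the ridge and KNN baselines.

test_that("the multi-task loss matches hand arithmetic on the one-sample example", {
  # y0 = (1, 0), y0hat = (0, 0), y1 = (1), y1hat = (0), w0 = 2.2, w1 = 1:
  # L = 2.2 * 1 + 1 * 1 = 3.2 (sum over dimensions, mean over the 1 sample)
  fw <- list(out = matrix(c(0, 0), 2, 1), h = matrix(0, 1, 1))
  l <- actdecode:::mlp_loss_t(fw, y0t = matrix(c(1, 0), 2, 1),
                              y1t = matrix(1, 1, 1), w0 = 2.2, w1 = 1)
  expect_equal(l, 3.2, tolerance = 1e-12)
})

test_that("with w1 = 0 the loss is w0 times the plain MSE-sum on y0", {
  set.seed(601)
  out <- matrix(rnorm(12), 4, 3)   # d0 x B feature-major blocks
  y0t <- matrix(rnorm(12), 4, 3)
  l <- actdecode:::mlp_loss_t(list(out = out, h = NULL), y0t, NULL,
                              w0 = 2.2, w1 = 0)
  expect_equal(l, 2.2 * sum((y0t - out)^2) / 3, tolerance = 1e-12)
})

test_that("analytic MLP gradients match finite differences", {
  set.seed(602)
  k <- 5L; h <- 4L; d0 <- 3L; B <- 6L
  Xt <- matrix(rnorm(k * B), k, B)
  y0t <- matrix(rnorm(d0 * B), d0, B)
  y1t <- matrix(rnorm(h * B), h, B)
  par <- with_seed <- NULL
  par <- withr::with_seed(7, actdecode:::mlp_init(k, h, d0, batch_norm = TRUE))
  loss_at <- function(p) {
    fw <- actdecode:::mlp_forward_t(p, Xt, dropout = 0, training = TRUE)
    actdecode:::mlp_loss_t(fw, y0t, y1t, w0 = 2.2, w1 = 1)
  }
  fw <- actdecode:::mlp_forward_t(par, Xt, dropout = 0, training = TRUE)
  gr <- actdecode:::mlp_backward_t(par, Xt, fw, y0t, y1t,
                                   w0 = 2.2, w1 = 1, dropout = 0)
  eps <- 1e-6
  for (nm in c("W1", "b1", "gamma", "beta", "W2", "b2")) {
    idx <- sample(length(par[[nm]]), min(4, length(par[[nm]])))
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("seeded training is reproducible and plain MLP is the degenerate multitask", {
  set.seed(603)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y0 <- matrix(rnorm(40 * 3), 40, 3)
  y1 <- matrix(rnorm(40 * 5), 40, 5)
  spec <- regressor_spec("multitask_mlp", hidden_dim = 5L, epochs = 20L,
                         seed = 9L)
  r1 <- suppressMessages(fit_regressor(X, y0, y1, spec))
  r2 <- suppressMessages(fit_regressor(X, y0, y1, spec))
  expect_equal(r1$loss_trace, r2$loss_trace, tolerance = 1e-6)
  expect_identical(r1$fit$par$W1, r2$fit$par$W1)

  # kind = "mlp" forces w1 = 0; identical seed => identical parameter path
  # to a multitask run with w1 manually zeroed
  sp_mlp <- regressor_spec("mlp", hidden_dim = 5L, epochs = 10L, seed = 4L)
  sp_mt0 <- regressor_spec("multitask_mlp", hidden_dim = 5L, epochs = 10L,
                           seed = 4L)
  sp_mt0$w1 <- 0
  a <- suppressMessages(fit_regressor(X, y0, NULL, sp_mlp))
  b <- suppressMessages(fit_regressor(X, y0, NULL, sp_mt0))
  expect_identical(a$fit$par$W2, b$fit$par$W2)
})

test_that("multitask fitting requires auxiliary targets of the hidden width", {
  X <- matrix(rnorm(30), 10, 3)
  y0 <- matrix(rnorm(20), 10, 2)
  spec <- regressor_spec("multitask_mlp", hidden_dim = 4L, epochs = 2L)
  expect_error(suppressMessages(fit_regressor(X, y0, NULL, spec)), "auxiliary")
  bad_y1 <- matrix(rnorm(30), 10, 3)
  expect_error(suppressMessages(fit_regressor(X, y0, bad_y1, spec)),
               "hidden_dim")
})

test_that("an overfit tiny MLP reproduces its training targets", {
  set.seed(604)
  X <- matrix(rnorm(8 * 4), 8, 4)
  y0 <- matrix(rnorm(8 * 2), 8, 2)
  spec <- regressor_spec("mlp", hidden_dim = 16L, dropout = 0,
                         batch_norm = FALSE, learning_rate = 1e-2,
                         batch_size = 8L, epochs = 3000L, seed = 2L)
  reg <- suppressMessages(fit_regressor(X, y0, NULL, spec))
  expect_lt(reg$loss_trace[length(reg$loss_trace)], 1e-3)
  pred <- predict(reg, X)
  expect_equal(pred, y0, tolerance = 0.05, ignore_attr = TRUE)
  # inference is deterministic: repeated identical rows agree exactly
  two <- predict(reg, X[c(1, 1), , drop = FALSE])
  expect_identical(two[1, ], two[2, ])
})

test_that("near-unregularized ridge recovers a noiseless linear map", {
  set.seed(605)
  n <- 50L; k <- 10L; d0 <- 4L
  X <- matrix(rnorm(n * k), n, k)
  B <- matrix(rnorm(k * d0), k, d0)
  y0 <- X %*% B
  spec <- regressor_spec("ridge", ridge_alpha = 1e-8, standardize = FALSE)
  reg <- fit_regressor(X, y0, spec = spec)
  Xnew <- matrix(rnorm(20 * k), 20, k)
  pred <- predict(reg, Xnew)
  truth <- Xnew %*% B
  expect_lt(max(abs(pred - truth)) / max(abs(truth)), 1e-4)
})

test_that("ridge agrees with lm() in the vanishing-penalty limit", {
  set.seed(606)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- X %*% rnorm(4) + rnorm(30, sd = 0.3)
  reg <- fit_regressor(X, matrix(y), spec = regressor_spec(
    "ridge", ridge_alpha = 1e-10, standardize = FALSE))
  ls <- lm(y ~ X)
  co <- coef(reg)
  expect_equal(unname(co[1, 1]), unname(coef(ls)[1]), tolerance = 1e-6)
  expect_equal(unname(co[-1, 1]), unname(coef(ls)[-1]), tolerance = 1e-6)
})

test_that("KNN with k = 1 returns the training target of the nearest point exactly", {
  set.seed(607)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y0 <- matrix(rnorm(12 * 2), 12, 2)
  reg <- fit_regressor(X, y0, spec = regressor_spec(
    "knn", knn_k = 1L, standardize = FALSE))
  pred <- predict(reg, X[5, , drop = FALSE])
  expect_identical(drop(pred), y0[5, ])
})

test_that("KNN averages the k nearest targets with uniform weights", {
  # 1-d layout where the 3 nearest neighbours of the query are known
  X <- matrix(c(0, 1, 2, 10, 11), 5, 1)
  y0 <- matrix(c(0, 10, 20, 100, 110), 5, 1)
  reg <- fit_regressor(X, y0, spec = regressor_spec(
    "knn", knn_k = 3L, standardize = FALSE))
  expect_equal(drop(predict(reg, matrix(0.9))), mean(c(0, 10, 20)))
})

test_that("standardization uses training statistics at prediction time", {
  set.seed(608)
  X <- matrix(rnorm(40 * 3, mean = 5, sd = 2), 40, 3)
  y0 <- matrix(rnorm(40 * 2), 40, 2)
  expect_message(
    reg <- fit_regressor(X, y0, spec = regressor_spec("ridge")),
    "z-scored")
  # shifting a prediction input changes output; shifting the training set
  # and inputs together does not (affine equivariance through z-scoring)
  reg2 <- suppressMessages(fit_regressor(X + 100, y0,
                                         spec = regressor_spec("ridge")))
  expect_equal(predict(reg, X[1:3, ]), predict(reg2, X[1:3, ] + 100),
               tolerance = 1e-8)
})

test_that("prediction rejects inputs of the wrong width and non-finite values", {
  X <- matrix(rnorm(30), 10, 3)
  y0 <- matrix(rnorm(10), 10, 1)
  reg <- fit_regressor(X, y0, spec = regressor_spec("ridge",
                                                    standardize = FALSE))
  expect_error(predict(reg, matrix(0, 2, 5)), "expects")
  expect_error(predict(reg, matrix(NA_real_, 2, 3)), "non-finite")
})
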