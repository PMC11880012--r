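test_that("certain predictions give perfect Top-k at every depth", {
  C <- 6L
  labels <- c(2L, 5L, 1L)
  Q <- matrix(1e-6, 3, C)
  Q[cbind(1:3, labels)] <- 1
  Q <- Q / rowSums(Q)
  expect_equal(topk_accuracy(Q, labels, 1), 100)
  expect_equal(topk_accuracy(Q, labels, 5), 100)
})

test_that("Top-k counts ranks correctly on a hand example", {
  # three stimuli whose true categories sit at ranks 1, 4 and 6
  C <- 8L
  Q <- matrix(0, 3, C)
  for (i in 1:3) Q[i, ] <- rev(seq_len(C)) / sum(seq_len(C))  # rank = index
  labels <- c(1L, 4L, 6L)
  expect_equal(per_stimulus_rank(Q, labels), c(1L, 4L, 6L))
  expect_equal(topk_accuracy(Q, labels, 1), 100 / 3, tolerance = 1e-10)
  expect_equal(topk_accuracy(Q, labels, 5), 200 / 3, tolerance = 1e-10)
})

test_that("Top-k validates labels and depth, and nests in k", {
  Q <- matrix(runif(20), 4, 5)
  expect_error(topk_accuracy(Q, c(1, 2, 6, 1), 1), "1\\.\\.5")
  expect_error(topk_accuracy(Q, c(1, 2, 3, 1), 9), "between 1")
  set.seed(801)
  Q2 <- matrix(runif(300), 30, 10)
  labels <- sample(10, 30, replace = TRUE)
  accs <- vapply(1:10, function(k) topk_accuracy(Q2, labels, k), numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[10], 100)
})

test_that("deterministic tie-breaking prefers the lower category index", {
  Q <- matrix(1 / 4, 2, 4)          # fully tied
  expect_equal(per_stimulus_rank(Q, c(1L, 4L)), c(1L, 4L))
  # randomized mode spreads tied ranks uniformly
  set.seed(802)
  r <- replicate(2000, per_stimulus_rank(Q[1, , drop = FALSE], 2L,
                                         tie_break = "random"))
  expect_equal(sort(unique(r)), 1:4)
  expect_equal(mean(r), 2.5, tolerance = 0.1)
})

test_that("pairwise identification is perfect for exact predictions and fails on ties", {
  set.seed(803)
  y <- matrix(rnorm(6 * 10), 6, 10)
  expect_equal(pairwise_classification(y, y), 100)
  # identical predictions for every stimulus: all comparisons tie -> 0
  same <- matrix(rep(rnorm(10), each = 6), 6, 10)
  expect_equal(pairwise_classification(same, y), 0)
})

test_that("the symmetric rule follows the summed-correlation arithmetic", {
  # construct vectors with a known 2x2 cross-correlation matrix
  # [[0.9, 0.1], [0.2, 0.8]] via an orthonormal centered basis
  base <- qr.Q(qr(cbind(1, matrix(rnorm(6 * 4), 6, 4))))[, 2:5]
  u1 <- base[, 1]; u2 <- base[, 2]; e1 <- base[, 3]; e2 <- base[, 4]
  truth <- rbind(u1, u2)
  p1 <- 0.9 * u1 + 0.1 * u2 + sqrt(1 - 0.9^2 - 0.1^2) * e1
  p2 <- 0.2 * u1 + 0.8 * u2 + sqrt(1 - 0.2^2 - 0.8^2) * e2
  pred <- rbind(p1, p2)
  R <- actdecode:::cross_row_cor(pred, truth)
  expect_equal(R, rbind(c(0.9, 0.1), c(0.2, 0.8)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # 0.9 + 0.8 > 0.1 + 0.2 -> the single pair is correct
  expect_equal(pairwise_classification(pred, truth), 100)
  # the one-sided rule agrees here (0.9 > 0.1 and 0.8 > 0.2)
  expect_equal(pairwise_classification(pred, truth, rule = "one_sided"), 100)
})

test_that("pairwise accuracy is invariant to a common stimulus permutation", {
  set.seed(804)
  yhat <- matrix(rnorm(8 * 12), 8, 12)
  y <- matrix(rnorm(8 * 12), 8, 12)
  base <- pairwise_classification(yhat, y)
  perm <- sample(8)
  expect_equal(pairwise_classification(yhat[perm, ], y[perm, ]), base)
})

test_that("constant vectors are scored with zero correlation and a warning", {
  y <- matrix(rnorm(3 * 5), 3, 5)
  yhat <- y
  yhat[2, ] <- 7   # constant prediction
  expect_warning(pairwise_classification(yhat, y), "constant")
  expect_error(pairwise_classification(y[1, , drop = FALSE],
                                       y[1, , drop = FALSE]), "2 stimuli")
})

test_that("true-category ranks are uniform under random predictions", {
  # permutation-null distribution check: with continuous random scores the
  # rank of the true category is uniform on 1..C
  set.seed(805)
  C <- 13L
  ranks <- integer(0)
  for (rep in 1:60) {
    Q <- matrix(rnorm(20 * C), 20, C)
    labels <- sample(C, 20, replace = TRUE)
    ranks <- c(ranks, per_stimulus_rank(Q, labels))
  }
  tab <- tabulate(ranks, C)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 1e-4)
})

test_that("LOSO on noise-free data is perfect and fully reproducible", {
  # jitter stays positive: identical same-class targets would create exact
  # pairwise ties, which the metric scores as incorrect by design
  ds <- tiny_dataset(noise_sd = 0, subject_gain_sd = 0)
  ev <- suppressWarnings(suppressMessages(
    run_loso(ds, spec = regressor_spec("ridge", seed = 3L))))
  expect_equal(ev$summary$top1, 100)
  expect_equal(ev$summary$pairwise, 100)
  ev2 <- suppressWarnings(suppressMessages(
    run_loso(ds, spec = regressor_spec("ridge", seed = 3L))))
  expect_identical(ev$summary, ev2$summary)
})

test_that("fold metrics nest (Top-5 >= Top-1) and the summary is the fold mean", {
  ds <- tiny_dataset()
  ev <- suppressWarnings(suppressMessages(
    run_loso(ds, spec = regressor_spec("knn"))))
  df <- as.data.frame(ev)
  expect_true(all(df$topk >= df$top1))
  expect_equal(ev$summary$top1, mean(df$top1))
  expect_equal(ev$summary$pairwise, mean(df$pairwise))
  expect_equal(nrow(df), length(ds$betas))
})

test_that("shuffling category labels collapses decoding to chance", {
  ds <- tiny_dataset(noise_sd = 0.2)
  shuffled <- ds
  set.seed(806)
  perm <- sample(nrow(ds$space$y0))
  # break the stimulus-to-feature correspondence seen by the decoder
  shuffled$space <- action_feature_space(ds$space$y0[perm, ],
                                         ds$space$y1[perm, ],
                                         ds$space$W, ds$space$b)
  ev_true <- suppressWarnings(suppressMessages(
    run_loso(ds, spec = regressor_spec("ridge"))))
  ev_null <- suppressWarnings(suppressMessages(
    run_loso(shuffled, spec = regressor_spec("ridge"))))
  expect_gt(ev_true$summary$top1, 90)
  # 6 categories -> chance 16.7% Top-1, 50% pairwise; allow broad noise
  expect_lt(ev_null$summary$top1, 45)
  expect_lt(abs(ev_null$summary$pairwise - 50), 25)
})

test_that("ROI decoding matches the whole-voxel run when the ROI is everything", {
  ds <- tiny_dataset()
  sp <- regressor_spec("ridge")
  whole <- suppressWarnings(suppressMessages(run_loso(ds, spec = sp)))
  rep <- suppressWarnings(suppressMessages(
    roi_decoding(ds, list(all = rep(TRUE, 60L)), spec = sp)))
  expect_equal(rep$all$summary, whole$summary)
})

test_that("pure-noise ROIs decode near chance and empty ROIs are skipped", {
  ds <- tiny_dataset()
  noise_roi <- rep(TRUE, 60L)
  noise_roi[ds$ground_truth$reliable_idx] <- FALSE
  sp <- regressor_spec("ridge")
  expect_warning(
    rep <- suppressMessages(roi_decoding(
      ds, list(noise = noise_roi, empty = rep(FALSE, 60L)), spec = sp,
      pca_k = 20L)),
    "empty")
  expect_null(rep$empty)
  planted <- rep(FALSE, 60L); planted[ds$ground_truth$reliable_idx] <- TRUE
  rep2 <- suppressWarnings(suppressMessages(roi_decoding(
    ds, list(planted = planted), spec = sp, pca_k = 20L)))
  expect_gt(rep2$planted$summary$top1, rep$noise$summary$top1)
  expect_lt(rep$noise$summary$top1, 45)   # chance is 16.7% for 6 classes
})
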