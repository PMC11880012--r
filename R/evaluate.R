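## Decoding metrics (Top-k, pairwise identification) and the
## leave-one-subject-out evaluation pipeline.

#' Top-k classification accuracy from category probabilities
#'
#' Ranks categories per stimulus in descending probability; a stimulus is
#' Top-k correct when its true category is among the k highest. Ties are
#' broken deterministically by ascending category index by default; the
#' `"random"` mode assigns tied categories a uniformly random order (used
#' for chance-level simulations, where the deterministic rule would be
#' degenerate on exactly uniform probabilities).
#'
#' @param Q samples x C probability (or score) matrix.
#' @param true_labels integer vector of true categories in `1..C`.
#' @param k rank depth (default 1).
#' @param tie_break `"index"` (default) or `"random"`.
#' @return accuracy in percent.
#' @export
topk_accuracy <- function(Q, true_labels, k = 1L, tie_break = c("index", "random")) {
  tie_break <- match.arg(tie_break)
  if (k < 1L || k > ncol(as.matrix(Q)))
    stop("k must lie between 1 and the number of categories")
  r <- per_stimulus_rank(Q, true_labels, tie_break)
  mean(r <= k) * 100
}

#' Rank of the true category per stimulus
#'
#' @inheritParams topk_accuracy
#' @return integer vector of ranks (1 = highest probability).
#' @export
per_stimulus_rank <- function(Q, true_labels, tie_break = c("index", "random")) {
  tie_break <- match.arg(tie_break)
  Q <- as.matrix(Q)
  C <- ncol(Q)
  true_labels <- as.integer(true_labels)
  if (any(true_labels < 1L | true_labels > C))
    stop(sprintf("labels must lie in 1..%d", C))
  vapply(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    qt <- q[true_labels[i]]
    higher <- sum(q > qt)
    ties <- sum(q == qt) - 1L
    offset <- if (ties == 0L) 0L
      else if (tie_break == "index") sum(q == qt & seq_len(C) < true_labels[i])
      else sample.int(ties + 1L, 1L) - 1L
    as.integer(higher + offset + 1L)
  }, integer(1))
}

#' Pairwise identification accuracy of predicted feature vectors
#'
#' Over all unordered stimulus pairs (i, j), the pair is decoded correctly
#' when the predictions match their own targets better than the swapped
#' assignment: `corr(yhat_i, y_i) + corr(yhat_j, y_j) > corr(yhat_i, y_j) +
#' corr(yhat_j, y_i)` (the symmetric sum rule, the default). The
#' `"one_sided"` rule instead requires each prediction separately to
#' correlate best with its own target. Ties count as incorrect; constant
#' vectors get correlation 0 with a warning. Chance level is 50% for both
#' rules.
#'
#' @param y0_hat samples x d matrix of predicted feature vectors.
#' @param y0_true samples x d matrix of true feature vectors (same order).
#' @param rule `"symmetric"` (default) or `"one_sided"`.
#' @return accuracy in percent.
#' @export
pairwise_classification <- function(y0_hat, y0_true,
                                    rule = c("symmetric", "one_sided")) {
  rule <- match.arg(rule)
  y0_hat <- as.matrix(y0_hat); y0_true <- as.matrix(y0_true)
  stopifnot(all(dim(y0_hat) == dim(y0_true)))
  n <- nrow(y0_hat)
  if (n < 2L) stop("pairwise classification needs at least 2 stimuli")
  R <- cross_row_cor(y0_hat, y0_true)     # R[i, j] = corr(yhat_i, y_j)
  correct <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- if (rule == "symmetric")
      R[i, i] + R[j, j] > R[i, j] + R[j, i]
    else
      R[i, i] > R[i, j] && R[j, j] > R[j, i]
    correct <- correct + ok
    total <- total + 1L
  }
  correct / total * 100
}

## Row-by-row cross correlation matrix between two sets of vectors;
## constant rows are scored 0 (with a warning), matching the package-wide
## convention for undefined Pearson correlations.
cross_row_cor <- function(A, B) {
  std <- function(M) {
    Mc <- M - rowMeans(M)
    nrm <- sqrt(rowSums(Mc^2))
    z <- nrm == 0
    if (any(z)) {
      warning("constant feature vectors: correlation defined as 0")
      nrm[z] <- Inf
    }
    Mc / nrm
  }
  tcrossprod(std(A), std(B))
}

#' Leave-one-subject-out decoding evaluation
#'
#' For each fold: fits PCA on the training subjects' mean beta patterns
#' only, optionally mixup-augments the reduced training set (training-fold
#' subjects only — the held-out subject never contributes), trains the
#' regressor, predicts the held-out subject's action features, applies the
#' softmax readout, and scores Top-1, Top-k and pairwise identification.
#' The summary is the unweighted mean across folds.
#'
#' @param dataset list with `betas` (list of `subject_betas`), `table`
#'   (a `stimulus_table`) and `space` (an `action_feature_space`), e.g.
#'   from [simulate_dataset()] or [read_dataset_bundle()].
#' @param spec a `regressor_spec`; each fold derives its own seed from
#'   `spec$seed` and the fold index.
#' @param aug_config optional `augmentation_config`; `NULL` disables
#'   augmentation.
#' @param voxel_mask optional logical/index vector restricting the voxels
#'   (e.g. a reliability mask or an ROI).
#' @param pca_k requested PCA components (default 1000, capped at rank).
#' @param top_k secondary rank depth (default 5).
#' @return An object of class `loso_evaluation`: per-fold results and a
#'   `summary` row of mean metrics.
#' @export
run_loso <- function(dataset, spec = regressor_spec(), aug_config = NULL,
                     voxel_mask = NULL, pca_k = 1000L, top_k = 5L) {
  betas <- dataset$betas
  table <- dataset$table
  space <- dataset$space
  if (length(betas) < 2L) stop("leave-one-subject-out requires >= 2 subjects")
  has_readout <- !is.null(space$W)
  mats <- lapply(betas, function(sb) {
    m <- subject_matrix(sb)
    if (!is.null(voxel_mask)) m <- m[, voxel_mask, drop = FALSE]
    m
  })
  if (ncol(mats[[1]]) < 1L) stop("voxel mask leaves no voxels")
  n_stim <- nrow(table)
  folds <- vector("list", length(betas))
  for (f in seq_along(betas)) {
    res <- tryCatch({
      train_ids <- setdiff(seq_along(betas), f)
      Xtr <- do.call(rbind, mats[train_ids])
      red <- fit_pca(Xtr, k = pca_k)
      Str <- apply_pca(red, Xtr)
      Ste <- apply_pca(red, mats[[f]])
      Y0 <- space$y0[rep(seq_len(n_stim), length(train_ids)), , drop = FALSE]
      Y1 <- if (!is.null(space$y1))
        space$y1[rep(seq_len(n_stim), length(train_ids)), , drop = FALSE]
      subj <- rep(vapply(betas[train_ids], `[[`, "", "subject_id"),
                  each = n_stim)
      categ <- rep(table$category, length(train_ids))
      if (!is.null(aug_config)) {
        aug <- mixup_augment(Str, Y0, Y1, subject = subj, category = categ,
                             config = augmentation_config(
                               lambda_mode = aug_config$lambda_mode,
                               lambda_value = aug_config$lambda_value,
                               alpha = aug_config$alpha,
                               n_new_per_class = aug_config$n_new_per_class,
                               restrict_same_class = aug_config$restrict_same_class,
                               restrict_cross_subject = aug_config$restrict_cross_subject,
                               seed = derive_seed(aug_config$seed, f)))
        Str <- aug$X; Y0 <- aug$y0; Y1 <- aug$y1
      }
      fold_spec <- spec
      fold_spec$seed <- derive_seed(spec$seed, f)
      reg <- fit_regressor(Str, Y0, Y1, fold_spec)
      y0_hat <- predict(reg, Ste)
      pw <- pairwise_classification(y0_hat, space$y0)
      if (has_readout) {
        Q <- softmax_readout(y0_hat, space$W, space$b)
        ranks <- per_stimulus_rank(Q, table$category)
        top1 <- mean(ranks <= 1L) * 100
        topk <- mean(ranks <= top_k) * 100
      } else {
        Q <- NULL; ranks <- rep(NA_integer_, n_stim)
        top1 <- NA_real_; topk <- NA_real_
      }
      list(fold_subject = betas[[f]]$subject_id,
           Q = Q, y0_hat = y0_hat,
           top1 = top1, topk = topk, top_k = top_k, pairwise = pw,
           per_stimulus_rank = ranks, k_eff = red$k_eff)
    }, error = function(e) {
      stop(sprintf("fold %d (subject %s) failed: %s",
                   f, betas[[f]]$subject_id, conditionMessage(e)))
    })
    folds[[f]] <- res
  }
  summ <- data.frame(
    top1 = mean(vapply(folds, `[[`, 0, "top1")),
    topk = mean(vapply(folds, `[[`, 0, "topk")),
    pairwise = mean(vapply(folds, `[[`, 0, "pairwise")))
  structure(list(folds = folds, summary = summ, top_k = top_k,
                 spec = spec, augmented = !is.null(aug_config),
                 n_voxels = ncol(mats[[1]])),
            class = "loso_evaluation")
}

#' @export
print.loso_evaluation <- function(x, ...) {
  cat(sprintf("LOSO decoding evaluation: %d folds, %d voxels%s\n",
              length(x$folds), x$n_voxels,
              if (x$augmented) ", mixup-augmented" else ""))
  cat(sprintf("  mean Top-1 %.2f%%, Top-%d %.2f%%, pairwise %.2f%%\n",
              x$summary$top1, x$top_k, x$summary$topk, x$summary$pairwise))
  invisible(x)
}

#' @export
summary.loso_evaluation <- function(object, ...) {
  print(object)
  df <- as.data.frame(object)
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.loso_evaluation <- function(x, ...) {
  data.frame(
    fold_subject = vapply(x$folds, `[[`, "", "fold_subject"),
    top1 = vapply(x$folds, `[[`, 0, "top1"),
    topk = vapply(x$folds, `[[`, 0, "topk"),
    pairwise = vapply(x$folds, `[[`, 0, "pairwise"),
    k_eff = vapply(x$folds, `[[`, 0L, "k_eff"))
}

#' @export
plot.loso_evaluation <- function(x, ...) {
  df <- as.data.frame(x)
  graphics::barplot(rbind(df$top1, df$topk), beside = TRUE,
                    names.arg = df$fold_subject, las = 2,
                    legend.text = c("Top-1", sprintf("Top-%d", x$top_k)),
                    ylab = "accuracy (%)", ...)
  invisible(x)
}

#' ROI-restricted leave-one-subject-out decoding
#'
#' Repeats [run_loso()] with the voxel set restricted to each region of
#' interest; when a reliability mask is supplied the intersection is taken
#' ROI-first (`ROI & reliable`) and logged. Empty ROIs are skipped with a
#' warning.
#'
#' @param dataset as in [run_loso()].
#' @param roi_masks named list of logical voxel masks (or index vectors).
#' @param reliability_mask optional logical mask intersected with each ROI.
#' @param ... passed to [run_loso()] (`spec`, `aug_config`, `pca_k`, ...).
#' @return A named list of `loso_evaluation`s of class `roi_report`.
#' @export
roi_decoding <- function(dataset, roi_masks, reliability_mask = NULL, ...) {
  nv <- ncol(subject_matrix(dataset$betas[[1]]))
  out <- list()
  for (nm in names(roi_masks)) {
    m <- roi_masks[[nm]]
    if (!is.logical(m)) {
      idx <- as.integer(m)
      m <- rep(FALSE, nv); m[idx] <- TRUE
    }
    if (!is.null(reliability_mask)) m <- m & reliability_mask
    message(sprintf("ROI %s: %d voxels after intersection", nm, sum(m)))
    if (!any(m)) {
      warning(sprintf("ROI %s is empty after intersection: skipped", nm))
      next
    }
    out[[nm]] <- run_loso(dataset, voxel_mask = m, ...)
  }
  class(out) <- "roi_report"
  out
}

#' @export
print.roi_report <- function(x, ...) {
  cat("ROI decoding report\n")
  for (nm in names(x)) {
    s <- x[[nm]]$summary
    cat(sprintf("  %-20s Top-1 %6.2f%%  Top-%d %6.2f%%  pairwise %6.2f%%\n",
                nm, s$top1, x[[nm]]$top_k, s$topk, s$pairwise))
  }
  invisible(x)
}
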