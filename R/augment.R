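## Mixup-style cross-subject data augmentation: convex interpolation of
## same-category, different-subject PCA-reduced samples and their targets.

#' Configuration for mixup augmentation
#'
#' New training samples are built as `d = lambda * d_si + (1 - lambda) *
#' d_sj` with the target interpolated by the same weight. By default the
#' mixing weight is fixed at 0.2 (the selected value); `lambda_mode =
#' "beta"` instead draws `lambda ~ Beta(alpha, alpha)` per new sample.
#'
#' @param lambda_mode `"fixed"` (default) or `"beta"`.
#' @param lambda_value mixing weight in `[0, 1]` for fixed mode
#'   (default 0.2).
#' @param alpha positive Beta shape for beta mode (default 0.2).
#' @param n_new_per_class new samples per category; `NULL` (default) means
#'   one per training subject, roughly doubling the training set.
#' @param restrict_same_class pair only samples of the same category
#'   (default TRUE; turning this off leaves augmented labels undefined).
#' @param restrict_cross_subject pair only samples of different subjects
#'   (default TRUE).
#' @param seed integer seed for pair and lambda draws.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(lambda_mode = c("fixed", "beta"),
                                lambda_value = 0.2, alpha = 0.2,
                                n_new_per_class = NULL,
                                restrict_same_class = TRUE,
                                restrict_cross_subject = TRUE,
                                seed = 1L) {
  lambda_mode <- match.arg(lambda_mode)
  if (lambda_value < 0 || lambda_value > 1)
    stop("lambda_value must lie in [0, 1]")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(lambda_mode = lambda_mode, lambda_value = lambda_value,
                 alpha = alpha,
                 n_new_per_class = if (is.null(n_new_per_class)) NULL
                                   else as.integer(n_new_per_class),
                 restrict_same_class = isTRUE(restrict_same_class),
                 restrict_cross_subject = isTRUE(restrict_cross_subject),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Mixup augmentation of reduced training samples
#'
#' Draws, for every category, uniformly random (same-category,
#' cross-subject) sample pairs and interpolates inputs and both target
#' blocks with one shared weight per new sample. Originals are always
#' retained: the returned matrices stack them above the augmented rows.
#'
#' @param X samples x k matrix of PCA-reduced training inputs.
#' @param y0 samples x d0 primary targets.
#' @param y1 optional samples x d1 auxiliary targets.
#' @param subject per-row subject identifier.
#' @param category per-row category label.
#' @param config an `augmentation_config`.
#' @return list with the stacked `X`, `y0`, `y1`, `subject` (augmented rows
#'   tagged `"mix"`), `category`, and `provenance` (data.frame: new row id,
#'   parent row indices, lambda, category).
#' @export
mixup_augment <- function(X, y0, y1 = NULL, subject, category,
                          config = augmentation_config()) {
  stopifnot(inherits(config, "augmentation_config"))
  X <- as.matrix(X); y0 <- as.matrix(y0)
  n <- nrow(X)
  if (length(subject) != n || length(category) != n)
    stop("subject and category must tag every row of X")
  if (!is.null(y1)) y1 <- as.matrix(y1)
  cats <- sort(unique(category))
  n_subj <- length(unique(subject))
  n_new <- config$n_new_per_class %||% n_subj

  with_seed(config$seed, {
    prov <- vector("list", length(cats))
    for (ci in seq_along(cats)) {
      rows <- which(category == cats[ci])
      if (config$restrict_same_class && length(rows) < 2L)
        stop(sprintf("category %s has a single sample: cannot pair", cats[ci]))
      if (config$restrict_cross_subject &&
          length(unique(subject[rows])) < 2L)
        stop(sprintf("category %s has samples from a single subject: cannot pair cross-subject",
                     cats[ci]))
      i <- integer(n_new); j <- integer(n_new)
      for (t in seq_len(n_new)) {
        repeat {
          p <- rows[sample.int(length(rows), 2L)]
          if (!config$restrict_cross_subject ||
              subject[p[1]] != subject[p[2]]) break
        }
        i[t] <- p[1]; j[t] <- p[2]
      }
      lam <- if (config$lambda_mode == "fixed")
        rep(config$lambda_value, n_new)
      else rbeta(n_new, config$alpha, config$alpha)
      prov[[ci]] <- data.frame(parent_i = i, parent_j = j, lambda = lam,
                               category = cats[ci])
    }
    prov <- do.call(rbind, prov)
    lam <- prov$lambda
    mix <- function(M) lam * M[prov$parent_i, , drop = FALSE] +
      (1 - lam) * M[prov$parent_j, , drop = FALSE]
    newX <- mix(X); new0 <- mix(y0)
    new1 <- if (!is.null(y1)) mix(y1) else NULL
    prov <- cbind(new_id = n + seq_len(nrow(prov)), prov)
    list(X = rbind(X, newX),
         y0 = rbind(y0, new0),
         y1 = if (is.null(y1)) NULL else rbind(y1, new1),
         subject = c(subject, rep("mix", nrow(prov))),
         category = c(category, prov$category),
         provenance = prov)
  })
}
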