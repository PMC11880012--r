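## PCA reduction of voxel responses, fitted on training-fold rows only.

#' Fit a PCA reduction of beta patterns
#'
#' Centers the training rows and extracts up to `k` principal components
#' (via [stats::prcomp()]). The effective component count is capped at the
#' data rank, `min(k, n_samples - 1, n_voxels)`; when the cap bites — as it
#' necessarily does for the nominal 1,000 components with 12 training subjects of 39
#' stimuli each — a warning reports the reduction rather than hiding it.
#'
#' @param train_betas samples x voxels numeric matrix (training rows only).
#' @param k requested number of components (default 1000).
#' @return An object of class `pca_reduction` with orthonormal `components`
#'   (k_eff x voxels), voxel `means`, `k_eff` and per-component
#'   `explained_variance`.
#' @export
fit_pca <- function(train_betas, k = 1000L) {
  train_betas <- as.matrix(train_betas)
  check_finite(train_betas, "betas")
  n <- nrow(train_betas)
  if (n < 2L) stop("PCA requires at least 2 samples")
  k_eff <- min(as.integer(k), n - 1L, ncol(train_betas))
  if (k_eff < k)
    warning(sprintf(
      "requested %d components but data rank allows only %d (capped at min(n_samples - 1, n_voxels))",
      as.integer(k), k_eff))
  p <- stats::prcomp(train_betas, center = TRUE, scale. = FALSE, rank. = k_eff)
  structure(list(components = t(p$rotation),      # k_eff x voxels
                 means = p$center,
                 k = as.integer(k), k_eff = k_eff,
                 explained_variance = p$sdev[seq_len(k_eff)]^2),
            class = "pca_reduction")
}

#' Project beta patterns onto a fitted PCA basis
#'
#' @param red a `pca_reduction`.
#' @param betas samples x voxels matrix on the same voxel grid.
#' @return samples x k_eff score matrix.
#' @export
apply_pca <- function(red, betas) {
  stopifnot(inherits(red, "pca_reduction"))
  betas <- as.matrix(betas)
  if (ncol(betas) != length(red$means))
    stop("voxel count does not match the fitted PCA")
  sweep(betas, 2L, red$means) %*% t(red$components)
}

#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  apply_pca(object, newdata)
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("PCA reduction: %d components (requested %d) over %d voxels\n",
              x$k_eff, x$k, length(x$means)))
  invisible(x)
}
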