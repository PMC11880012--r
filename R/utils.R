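## Internal helpers shared across modules.

#' @importFrom stats cor prcomp rnorm runif rbeta sd var predict
#' @importFrom utils head modifyList
NULL

## Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
## A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

## Derive a child seed from a base seed and a stream index; kept well below
## 2^31 so it survives as.integer().
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(stream) * 7919L) %% 2147483544L + 1L
}

## Pearson correlation with the convention r := 0 for constant series
## (zero-variance vectors have no defined correlation; a constant voxel
## carries no stimulus information, so 0 is the faithful score).
safe_cor <- function(x, y, warn = FALSE) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    if (warn) warning("constant series: correlation defined as 0")
    return(0)
  }
  stats::cor(x, y)
}

## Column-wise split-half correlation between two matrices (stimuli x voxels),
## constant columns scored 0. Vectorised: single pass, no per-voxel loop.
colwise_cor <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 stimuli to correlate odd/even halves")
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  r <- ifelse(den > 0, num / den, 0)
  ## clamp tiny floating-point excursions outside [-1, 1]
  pmin(1, pmax(-1, r))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
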