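## Split-half voxel reliability: per-voxel odd/even-run correlations
## (within-set and cross-set), the cutoff-curve diagnostic, and
## reliability-based voxel selection.

#' Per-voxel split-half reliability
#'
#' For every voxel, Pearson-correlates the mean beta over odd-indexed runs
#' with the mean over even-indexed runs, across stimuli. `within_set`
#' computes the correlation inside each video set separately and averages
#' the resulting r-maps; `cross_set` correlates set-1 odd betas with set-2
#' even betas (and the converse, averaged), pairing stimuli of the two sets
#' by category. Constant series are scored r = 0. With a single video set,
#' `cross_set` falls back to the single set's halves and the result is
#' flagged (`single_set = TRUE`).
#'
#' @param betas a `subject_betas`, or a list of them (averaged into a group
#'   map first, the convention used for group-level selection).
#' @param mode `"within_set"` or `"cross_set"`.
#' @return An object of class `reliability_result` with fields `r`
#'   (per-voxel reliability), `mode`, `single_set`, and the odd/even half
#'   matrices used (for the cutoff curve).
#' @export
voxel_split_half <- function(betas, mode = c("within_set", "cross_set")) {
  mode <- match.arg(mode)
  if (is.list(betas) && !inherits(betas, "subject_betas"))
    betas <- group_average(betas)
  stopifnot(inherits(betas, "subject_betas"))
  table <- betas$table
  halves <- odd_even_means(betas)
  sets <- sort(unique(table$set_id))
  single_set <- length(sets) == 1L

  if (mode == "within_set" || single_set) {
    rmaps <- lapply(sets, function(s) {
      rows <- which(table$set_id == s)
      if (length(rows) < 3L)
        stop(sprintf("set %d has fewer than 3 stimuli: correlation ill-defined", s))
      colwise_cor(halves$odd[rows, , drop = FALSE],
                  halves$even[rows, , drop = FALSE])
    })
    r <- Reduce(`+`, rmaps) / length(rmaps)
  } else {
    p <- pair_sets_by_category(table)
    if (nrow(p) < 3L) stop("fewer than 3 category-matched pairs across sets")
    r1 <- colwise_cor(halves$odd[p$set1, , drop = FALSE],
                      halves$even[p$set2, , drop = FALSE])
    r2 <- colwise_cor(halves$odd[p$set2, , drop = FALSE],
                      halves$even[p$set1, , drop = FALSE])
    r <- (r1 + r2) / 2
  }
  structure(list(r = r, mode = mode, single_set = single_set,
                 odd = halves$odd, even = halves$even, table = table),
            class = "reliability_result")
}

## Pair set-1 rows with set-2 rows by category label (the only well-defined
## pairing when exemplars are not matched across sets).
pair_sets_by_category <- function(table) {
  i1 <- which(table$set_id == 1L)
  i2 <- which(table$set_id == 2L)
  pairs <- lapply(sort(unique(table$category)), function(cl) {
    a <- i1[table$category[i1] == cl]
    b <- i2[table$category[i2] == cl]
    k <- min(length(a), length(b))
    if (k == 0L) return(NULL)
    data.frame(set1 = a[seq_len(k)], set2 = b[seq_len(k)])
  })
  do.call(rbind, pairs)
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Split-half reliability (%s%s): %d voxels\n", x$mode,
              if (x$single_set) ", single set" else "", length(x$r)))
  cat(sprintf("  r: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$r), min(x$r), max(x$r)))
  if (!is.null(x$cutoff))
    cat(sprintf("  cutoff %.2f: %d voxels selected\n",
                x$cutoff, sum(x$mask)))
  invisible(x)
}

#' Multi-voxel pattern reliability across candidate cutoffs
#'
#' For each candidate cutoff, restricts to voxels whose split-half r meets
#' the candidate, then correlates every video's odd-half multi-voxel
#' pattern with its even-half pattern over the surviving voxels. Plotting
#' the per-video reliabilities against the candidates shows where pattern
#' reliability stabilizes, which motivates the default voxel cutoff.
#' A candidate leaving fewer than 2 voxels yields `NA` entries (flagged,
#' not an error).
#'
#' @param rel a `reliability_result` from [voxel_split_half()].
#' @param candidates ascending numeric vector of candidate cutoffs.
#' @return matrix of pattern reliabilities, candidates x stimuli, with the
#'   surviving voxel count per candidate as attribute `n_voxels`.
#' @export
cutoff_curve <- function(rel, candidates = seq(-0.1, 0.9, by = 0.05)) {
  stopifnot(inherits(rel, "reliability_result"))
  if (is.unsorted(candidates)) stop("candidates must be sorted ascending")
  n_stim <- nrow(rel$odd)
  out <- matrix(NA_real_, length(candidates), n_stim,
                dimnames = list(sprintf("%.3f", candidates),
                                rel$table$stimulus_id))
  nvox <- integer(length(candidates))
  for (i in seq_along(candidates)) {
    keep <- rel$r >= candidates[i]
    nvox[i] <- sum(keep)
    if (nvox[i] < 2L) next
    o <- rel$odd[, keep, drop = FALSE]
    e <- rel$even[, keep, drop = FALSE]
    out[i, ] <- vapply(seq_len(n_stim),
                       function(v) safe_cor(o[v, ], e[v, ]), numeric(1))
  }
  attr(out, "n_voxels") <- nvox
  attr(out, "candidates") <- candidates
  out
}

#' Heuristic cutoff suggestion from a cutoff curve
#'
#' Returns the first candidate at which the median per-video pattern
#' reliability gains less than `tol` per step. Reported for inspection
#' only; selection always uses the cutoff the caller passes (default 0.3).
#'
#' @param curve output of [cutoff_curve()].
#' @param tol minimum median gain per step (default 0.005).
#' @return a single candidate cutoff value.
#' @export
suggest_cutoff <- function(curve, tol = 0.005) {
  cand <- attr(curve, "candidates")
  med <- apply(curve, 1L, stats::median, na.rm = TRUE)
  ok <- which(is.finite(med))
  if (length(ok) < 2L) return(cand[ok[1]])
  gains <- diff(med[ok])
  hit <- which(gains < tol)
  if (length(hit) == 0L) return(cand[ok[length(ok)]])
  cand[ok[hit[1] + 1L]]
}

#' Select reliable voxels at a cutoff
#'
#' Boundary is inclusive: a voxel passes when `r >= cutoff` ("0.3 or
#' higher").
#'
#' @param rel a `reliability_result` or a plain numeric r-map.
#' @param cutoff reliability cutoff in `[-1, 1]` (default 0.3).
#' @return logical voxel mask; when `rel` is a `reliability_result` the
#'   object is returned with `mask` and `cutoff` fields filled in instead.
#' @export
select_voxels <- function(rel, cutoff = 0.3) {
  if (cutoff < -1 || cutoff > 1) stop("cutoff must lie in [-1, 1]")
  r <- if (inherits(rel, "reliability_result")) rel$r else as.numeric(rel)
  mask <- r >= cutoff
  message(sprintf("reliability cutoff %.2f: %d of %d voxels selected",
                  cutoff, sum(mask), length(mask)))
  if (inherits(rel, "reliability_result")) {
    rel$cutoff <- cutoff
    rel$mask <- mask
    return(rel)
  }
  mask
}
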