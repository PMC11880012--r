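## Per-subject GLM beta containers and run-half arithmetic.

#' Construct a per-subject beta container
#'
#' Holds one subject's GLM beta estimates as one stimuli x voxels matrix per
#' run, in the row order of the stimulus table. All subjects in a dataset
#' must share the voxel grid (group-space analysis), which
#' [group_average()] and the decoding pipeline check.
#'
#' @param subject_id identifier.
#' @param betas_by_run named list of stimuli x voxels numeric matrices, one
#'   per run; an even run count is required so odd/even split halves exist.
#' @param table the `stimulus_table` fixing row order and set membership.
#' @param roi_labels optional character vector of per-voxel ROI labels.
#' @return An object of class `subject_betas`.
#' @export
subject_betas <- function(subject_id, betas_by_run, table, roi_labels = NULL) {
  if (length(betas_by_run) < 2L)
    stop("at least 2 runs are required (no split-half otherwise)")
  dims <- vapply(betas_by_run, dim, integer(2))
  if (any(dims[1, ] != nrow(table)))
    stop("every run must have one row per stimulus, in stimulus-table order")
  if (length(unique(dims[2, ])) != 1L)
    stop("voxel count must be identical across runs")
  structure(list(subject_id = as.character(subject_id),
                 betas_by_run = betas_by_run,
                 table = table,
                 roi_labels = roi_labels),
            class = "subject_betas")
}

#' @export
print.subject_betas <- function(x, ...) {
  cat(sprintf("Subject %s: %d runs, %d stimuli x %d voxels\n",
              x$subject_id, length(x$betas_by_run),
              nrow(x$betas_by_run[[1]]), ncol(x$betas_by_run[[1]])))
  invisible(x)
}

n_voxels <- function(sb) ncol(sb$betas_by_run[[1]])

## Mean beta over odd-indexed and even-indexed runs.
odd_even_means <- function(sb) {
  runs <- sb$betas_by_run
  idx <- seq_along(runs)
  avg <- function(i) Reduce(`+`, runs[i]) / length(i)
  list(odd = avg(idx[idx %% 2L == 1L]), even = avg(idx[idx %% 2L == 0L]))
}

#' Mean beta matrix over all runs of one subject
#'
#' @param sb a `subject_betas` object.
#' @return stimuli x voxels matrix.
#' @export
subject_matrix <- function(sb) {
  Reduce(`+`, sb$betas_by_run) / length(sb$betas_by_run)
}

#' Average beta maps across subjects, run by run
#'
#' Group-level reliability (the default in practice) correlates run halves
#' of the subject-averaged betas rather than of a single subject.
#'
#' @param betas_list list of `subject_betas` on a shared voxel grid.
#' @return A `subject_betas` with `subject_id = "group"`.
#' @export
group_average <- function(betas_list) {
  stopifnot(length(betas_list) >= 1L)
  nv <- vapply(betas_list, n_voxels, integer(1))
  if (length(unique(nv)) != 1L)
    stop("subjects must share the voxel grid to be averaged")
  n_runs <- vapply(betas_list, function(s) length(s$betas_by_run), integer(1))
  if (length(unique(n_runs)) != 1L)
    stop("subjects must share the run count to be averaged")
  runs <- lapply(seq_len(n_runs[1]), function(r) {
    Reduce(`+`, lapply(betas_list, function(s) s$betas_by_run[[r]])) /
      length(betas_list)
  })
  names(runs) <- names(betas_list[[1]]$betas_by_run)
  subject_betas("group", runs, betas_list[[1]]$table,
                betas_list[[1]]$roi_labels)
}
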