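## Readers and writers: the plain-text dataset bundle (the canonical
## interchange), NIfTI import/export for volumetric workflows, and
## evaluation outputs.

## Matrix payloads are written headerless at 17 significant digits, the
## precision at which IEEE doubles round-trip through text exactly.
write_matrix_csv <- function(m, path) {
  fm <- matrix(sprintf("%.17g", m), nrow(m))
  writeLines(apply(fm, 1L, paste, collapse = ","), path)
  invisible(path)
}

read_matrix_csv <- function(path) {
  if (!file.exists(path)) return(NULL)
  unname(as.matrix(data.table::fread(path, header = FALSE)))
}

#' Write / read a dataset bundle
#'
#' The canonical interchange is a directory of plain-text files: a
#' `stimuli.csv` table, one CSV beta matrix per subject and run under
#' `betas/`, the feature space under `feature_space/`, a `manifest.json`
#' (subjects, runs, voxel count), and — for synthetic data — a
#' `ground_truth.json` sidecar with the planted voxel indices and an
#' `encoding.csv` with the planted encoding vectors.
#'
#' @param dataset list with `table`, `space`, `betas` and optionally
#'   `ground_truth` and `config` (as returned by [simulate_dataset()]).
#' @param path bundle directory to create/read.
#' @return `read_dataset_bundle` returns a dataset list of the same shape.
#' @export
write_dataset_bundle <- function(dataset, path) {
  dir.create(file.path(path, "betas"), showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.frame(dataset$table), file.path(path, "stimuli.csv"))
  write_feature_space(dataset$space, file.path(path, "feature_space"))
  for (sb in dataset$betas) {
    for (rn in names(sb$betas_by_run)) {
      write_matrix_csv(sb$betas_by_run[[rn]],
                       file.path(path, "betas",
                                 sprintf("%s_%s.csv", sb$subject_id, rn)))
    }
  }
  gt <- dataset$ground_truth
  if (!is.null(gt)) {
    jsonlite::write_json(list(reliable_idx = gt$reliable_idx, gains = gt$gains),
                         file.path(path, "ground_truth.json"), digits = NA)
    write_matrix_csv(gt$encoding, file.path(path, "encoding.csv"))
  }
  manifest <- list(format = "actdecode-bundle", version = 1L,
                   subjects = vapply(dataset$betas, `[[`, "", "subject_id"),
                   runs = names(dataset$betas[[1]]$betas_by_run),
                   n_voxels = ncol(dataset$betas[[1]]$betas_by_run[[1]]),
                   config = unclass(dataset$config))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset_bundle
#' @export
read_dataset_bundle <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path))
    stop(sprintf("not a dataset bundle: missing %s", man_path))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(man$format, "actdecode-bundle"))
    stop("manifest.json does not describe an actdecode bundle")
  tab <- data.table::fread(file.path(path, "stimuli.csv"))
  table <- stimulus_table(tab$stimulus_id, tab$category, tab$set_id,
                          if ("category_name" %in% names(tab)) tab$category_name)
  space <- read_feature_space(file.path(path, "feature_space"))
  betas <- lapply(man$subjects, function(sid) {
    runs <- lapply(man$runs, function(rn) {
      f <- file.path(path, "betas", sprintf("%s_%s.csv", sid, rn))
      if (!file.exists(f))
        stop(sprintf("subject %s is missing run file %s", sid, basename(f)))
      m <- read_matrix_csv(f)
      if (nrow(m) != nrow(table) || ncol(m) != man$n_voxels)
        stop(sprintf("%s: expected %d x %d, found %d x %d",
                     basename(f), nrow(table), man$n_voxels, nrow(m), ncol(m)))
      m
    })
    names(runs) <- man$runs
    subject_betas(sid, runs, table)
  })
  gt <- NULL
  gtp <- file.path(path, "ground_truth.json")
  if (file.exists(gtp)) {
    g <- jsonlite::read_json(gtp, simplifyVector = TRUE)
    gt <- list(reliable_idx = as.integer(g$reliable_idx), gains = g$gains,
               encoding = read_matrix_csv(file.path(path, "encoding.csv")))
  }
  list(table = table, space = space, betas = betas, ground_truth = gt,
       config = man$config)
}

#' Read per-run beta volumes and a brain mask from NIfTI
#'
#' Volumes are flattened to stimuli x voxels matrices with the mask's
#' x-fastest voxel ordering (R's native array order), the documented
#' convention for all volumetric I/O in the package. Each run is a 4D
#' volume whose 4th dimension indexes stimuli in the order of the
#' stimulus table (a `stimulus_id` column in `order_csv` reorders rows to
#' table order when given).
#'
#' @param run_paths character vector of 4D NIfTI paths, one per run, in
#'   run order.
#' @param mask_path 3D NIfTI brain mask (nonzero = in-brain).
#' @param table the `stimulus_table`.
#' @param subject_id identifier for the returned container.
#' @param order_csv optional CSV with a `stimulus_id` column giving the
#'   row order of the volumes when it differs from the table.
#' @return A `subject_betas`.
#' @export
read_betas_nifti <- function(run_paths, mask_path, table,
                             subject_id = "subject", order_csv = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI input requires the RNifti package")
  mask <- as.array(RNifti::readNifti(mask_path)) != 0
  perm <- seq_len(nrow(table))
  if (!is.null(order_csv)) {
    ord <- data.table::fread(order_csv)
    perm <- match(table$stimulus_id, as.character(ord$stimulus_id))
    if (anyNA(perm)) stop("order_csv does not cover every stimulus id")
  }
  runs <- lapply(run_paths, function(p) {
    vol <- as.array(RNifti::readNifti(p))
    if (length(dim(vol)) != 4L)
      stop(sprintf("%s: expected a 4D volume", p))
    if (!all(dim(vol)[1:3] == dim(mask)))
      stop(sprintf("%s: volume/mask shape mismatch", p))
    flat <- matrix(vol, prod(dim(mask)), dim(vol)[4])
    t(flat[as.vector(mask), , drop = FALSE])[perm, , drop = FALSE]
  })
  names(runs) <- sprintf("run%d", seq_along(runs))
  subject_betas(subject_id, runs, table)
}

#' Write a per-voxel map (r-map or mask) as NIfTI
#'
#' @param values numeric or logical vector, one value per in-mask voxel in
#'   x-fastest order.
#' @param mask_path 3D NIfTI brain mask defining the voxel grid.
#' @param path output NIfTI path.
#' @return the output path, invisibly.
#' @export
write_nifti_map <- function(values, mask_path, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI output requires the RNifti package")
  ref <- RNifti::readNifti(mask_path)
  mask <- as.array(ref) != 0
  if (sum(mask) != length(values))
    stop("value count does not match the mask voxel count")
  vol <- array(0, dim(mask))
  vol[mask] <- as.numeric(values)
  RNifti::writeNifti(RNifti::asNifti(vol, reference = ref), path)
  invisible(path)
}

#' Write LOSO evaluation outputs
#'
#' Writes per-fold metrics as CSV, the fold-mean summary as JSON, and the
#' per-stimulus predicted category ranks as CSV.
#'
#' @param evaluation a `loso_evaluation`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.frame(evaluation),
                     file.path(dir, "fold_metrics.csv"))
  jsonlite::write_json(as.list(evaluation$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  ranks <- do.call(rbind, lapply(evaluation$folds, function(f)
    data.frame(fold_subject = f$fold_subject,
               stimulus = seq_along(f$per_stimulus_rank),
               true_rank = f$per_stimulus_rank)))
  data.table::fwrite(ranks, file.path(dir, "per_stimulus_rank.csv"))
  invisible(dir)
}

#' Write a reproducibility manifest
#'
#' Records the configuration, seed and loaded package versions of a run so
#' it can be reproduced from the manifest alone.
#'
#' @param config list of run settings.
#' @param seed the run seed.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  pkgs <- c("actdecode", "data.table", "jsonlite")
  vers <- vapply(pkgs, function(p)
    as.character(utils::packageVersion(p)), "")
  jsonlite::write_json(list(config = config, seed = seed,
                            package_versions = as.list(vers),
                            r_version = R.version.string,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
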