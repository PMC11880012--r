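## Stimulus table and deep action-feature space containers, plus the
## linear-softmax semantic readout that turns predicted features into
## category probabilities.

#' Construct a stimulus table
#'
#' The stimulus table defines the label space of the experiment: one row per
#' stimulus (video), with its semantic category and which of the two video
#' sets it belongs to. Categories must form the contiguous index set
#' `1..C` so they can be mapped one-to-one onto the rows of the softmax
#' readout weight matrix.
#'
#' @param stimulus_id character or integer vector of unique stimulus ids.
#' @param category integer vector of category labels in `1..C`.
#' @param set_id integer vector of video-set membership (1 or 2);
#'   defaults to set 1 for every stimulus.
#' @param category_name optional character vector of human-readable names.
#' @return A `data.frame` of class `stimulus_table`.
#' @export
stimulus_table <- function(stimulus_id, category, set_id = NULL,
                           category_name = NULL) {
  if (anyDuplicated(stimulus_id)) stop("stimulus ids must be unique")
  category <- as.integer(category)
  if (any(category < 1L)) stop("categories must be positive integers")
  C <- max(category)
  if (!setequal(unique(category), seq_len(C)))
    stop("categories must form the contiguous set 1..C")
  set_id <- if (is.null(set_id)) rep(1L, length(stimulus_id)) else as.integer(set_id)
  if (!all(set_id %in% c(1L, 2L))) stop("set_id must be 1 or 2")
  tab <- data.frame(stimulus_id = as.character(stimulus_id),
                    category = category,
                    set_id = set_id,
                    stringsAsFactors = FALSE)
  if (!is.null(category_name)) tab$category_name <- as.character(category_name)
  class(tab) <- c("stimulus_table", "data.frame")
  tab
}

n_categories <- function(table) max(table$category)

#' Construct an action-feature space
#'
#' Bundles the per-stimulus regression targets with the semantic readout of
#' the action-recognition network: `y0` are the action features (the
#' penultimate fully-connected output, the primary regression target,
#' default 128-dim), `y1` the auxiliary pooled features one layer earlier
#' (default 432-dim, target of the auxiliary loss term), and `(W, b)` the
#' final linear layer whose softmax converts predicted features into
#' category probabilities.
#'
#' @param y0 numeric matrix, stimuli x d0 action-feature targets.
#' @param y1 optional numeric matrix, stimuli x d1 auxiliary targets; when
#'   absent the multi-task loss is unavailable (its weight is forced to 0).
#' @param W optional numeric matrix, C x d0 readout weights; when absent,
#'   classification is unavailable (regression-only mode).
#' @param b optional numeric length-C readout bias (default zeros).
#' @param stimulus_id optional ids matching the rows of `y0`.
#' @return An object of class `action_feature_space`.
#' @export
action_feature_space <- function(y0, y1 = NULL, W = NULL, b = NULL,
                                 stimulus_id = NULL) {
  y0 <- as.matrix(y0)
  check_finite(y0, "y0")
  if (!is.null(y1)) {
    y1 <- as.matrix(y1)
    check_finite(y1, "y1")
    if (nrow(y1) != nrow(y0)) stop("y0 and y1 must have the same rows")
  }
  if (!is.null(W)) {
    W <- as.matrix(W)
    check_finite(W, "W")
    if (ncol(W) != ncol(y0)) stop("W columns must equal d0 = ncol(y0)")
    if (is.null(b)) b <- rep(0, nrow(W))
    if (length(b) != nrow(W)) stop("length(b) must equal nrow(W)")
    check_finite(b, "b")
  }
  structure(list(y0 = y0, y1 = y1, W = W, b = b,
                 stimulus_id = stimulus_id %||% rownames(y0)),
            class = "action_feature_space")
}

#' @export
print.action_feature_space <- function(x, ...) {
  cat("Action feature space\n")
  cat(sprintf("  stimuli: %d, d0: %d", nrow(x$y0), ncol(x$y0)))
  if (!is.null(x$y1)) cat(sprintf(", d1: %d", ncol(x$y1)))
  cat("\n")
  if (!is.null(x$W)) {
    cat(sprintf("  readout: %d categories\n", nrow(x$W)))
  } else {
    cat("  readout: absent (regression-only mode)\n")
  }
  invisible(x)
}

#' Linear-softmax semantic readout
#'
#' Converts predicted action features into category probabilities through
#' the network's final linear layer:
#' `Q[i, c] = exp(W_c . y_i + b_c) / sum_j exp(W_j . y_i + b_j)`.
#' Logits are max-shifted per row before exponentiation, so inputs of
#' magnitude 1e4 remain overflow-safe.
#'
#' @param y0_hat numeric matrix, samples x d0 predicted features.
#' @param W C x d0 readout weights.
#' @param b length-C bias (default zeros).
#' @return samples x C matrix of probabilities; each row sums to 1.
#' @export
softmax_readout <- function(y0_hat, W, b = NULL) {
  y0_hat <- as.matrix(y0_hat)
  W <- as.matrix(W)
  if (is.null(b)) b <- rep(0, nrow(W))
  check_finite(y0_hat, "y0_hat")
  check_finite(W, "W")
  check_finite(b, "b")
  if (ncol(y0_hat) != ncol(W)) stop("feature dimension mismatch with readout")
  logits <- y0_hat %*% t(W)
  logits <- sweep(logits, 2L, b, `+`)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  Q <- e / rowSums(e)
  dimnames(Q) <- list(rownames(y0_hat), rownames(W))
  Q
}

#' Write / read an action-feature space as a plain-text bundle
#'
#' The feature space is stored as a directory of CSV matrices
#' (`y0.csv`, `y1.csv`, `W.csv`, `b.csv`) plus a `space.json` sidecar with
#' dimensions and stimulus ids — one fixed schema, so axis order can never
#' be silently transposed.
#'
#' @param space an `action_feature_space`.
#' @param path directory to create/read.
#' @return `read_feature_space` returns an `action_feature_space`.
#' @export
write_feature_space <- function(space, path) {
  stopifnot(inherits(space, "action_feature_space"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) write_matrix_csv(m, file.path(path, f))
  wr(space$y0, "y0.csv")
  if (!is.null(space$y1)) wr(space$y1, "y1.csv")
  if (!is.null(space$W)) {
    wr(space$W, "W.csv")
    wr(matrix(space$b, ncol = 1L), "b.csv")
  }
  meta <- list(n_stimuli = nrow(space$y0), d0 = ncol(space$y0),
               d1 = if (is.null(space$y1)) NULL else ncol(space$y1),
               n_categories = if (is.null(space$W)) NULL else nrow(space$W),
               stimulus_id = space$stimulus_id)
  jsonlite::write_json(meta, file.path(path, "space.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  meta_path <- file.path(path, "space.json")
  if (!file.exists(meta_path))
    stop(sprintf("not a feature-space bundle (missing %s)", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  rd <- function(f) read_matrix_csv(file.path(path, f))
  y0 <- rd("y0.csv")
  if (is.null(y0)) stop("feature-space bundle lacks y0.csv")
  if (nrow(y0) != meta$n_stimuli || ncol(y0) != meta$d0)
    stop("y0.csv dimensions disagree with space.json")
  b <- rd("b.csv")
  action_feature_space(y0 = y0, y1 = rd("y1.csv"), W = rd("W.csv"),
                       b = if (is.null(b)) NULL else as.numeric(b),
                       stimulus_id = meta$stimulus_id)
}

#' Validate a feature space against a stimulus table
#'
#' Checks dimensions, finiteness and label coverage, and reports which
#' analysis modes the space supports. Missing `y1` downgrades the
#' multi-task loss (auxiliary weight forced to 0); missing `W` disables
#' classification.
#'
#' @param space an `action_feature_space`.
#' @param table a `stimulus_table`.
#' @return A list with elements `ok` (logical) and `issues`
#'   (character vector, empty when fully valid).
#' @export
validate_space <- function(space, table) {
  issues <- character()
  if (nrow(space$y0) != nrow(table))
    issues <- c(issues, sprintf("y0 has %d rows but stimulus table has %d",
                                nrow(space$y0), nrow(table)))
  if (is.null(space$y1))
    issues <- c(issues, "auxiliary targets missing: multi-task loss unavailable (w1 forced to 0)")
  if (is.null(space$W)) {
    issues <- c(issues, "readout missing: classification unavailable, regression-only mode")
  } else if (nrow(space$W) != n_categories(table)) {
    issues <- c(issues, sprintf("readout has %d rows but table has %d categories",
                                nrow(space$W), n_categories(table)))
  }
  hard <- !grepl("unavailable", issues)
  list(ok = !any(hard), issues = issues)
}
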