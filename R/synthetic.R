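## Synthetic multi-subject dataset generator: a feature space with a known
## softmax readout, and beta maps with a planted linear voxel encoding, so
## every stage of the decoding pipeline can be checked against ground truth.

#' Configuration for the synthetic dataset generator
#'
#' The generative model is deliberately the simplest one under which
#' reliability selection and PCA-plus-regression decoding are consistent:
#' class prototypes in action-feature space, a fixed random linear map to
#' the auxiliary feature space, a linear voxel encoding of the action
#' features with multiplicative subject gains, and additive iid Gaussian
#' run noise. Unreliable voxels are pure noise.
#'
#' @param n_classes number of semantic categories (default 39).
#' @param n_stimuli_per_class exemplars per category (default 1; with 2 or
#'   more, stimuli are tagged alternately video-set 1/2).
#' @param n_subjects number of subjects (default 13).
#' @param n_voxels total voxels per subject.
#' @param n_reliable_voxels voxels carrying the planted encoding.
#' @param d0,d1 action-feature and auxiliary feature dimensions
#'   (defaults 128 and 432).
#' @param prototype_spread sd of class prototypes in feature space
#'   (between-class scale, default 1).
#' @param within_class_jitter sd of per-exemplar jitter around the class
#'   prototype (0 makes classes perfectly separable).
#' @param noise_sd sd of additive per-run measurement noise.
#' @param subject_gain_sd sd of the multiplicative subject gain around 1.
#' @param n_runs number of runs; must be even so odd/even halves exist
#'   (default 8).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration including the seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 39L, n_stimuli_per_class = 1L,
                             n_subjects = 13L, n_voxels = 1000L,
                             n_reliable_voxels = 200L,
                             d0 = 128L, d1 = 432L,
                             prototype_spread = 1, within_class_jitter = 0.1,
                             noise_sd = 1, subject_gain_sd = 0.2,
                             n_runs = 8L, seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              n_stimuli_per_class = as.integer(n_stimuli_per_class),
              n_subjects = as.integer(n_subjects),
              n_voxels = as.integer(n_voxels),
              n_reliable_voxels = as.integer(n_reliable_voxels),
              d0 = as.integer(d0), d1 = as.integer(d1),
              prototype_spread = prototype_spread,
              within_class_jitter = within_class_jitter,
              noise_sd = noise_sd,
              subject_gain_sd = subject_gain_sd,
              n_runs = as.integer(n_runs),
              seed = as.integer(seed))
  with(cfg, {
    if (n_reliable_voxels > n_voxels)
      stop("n_reliable_voxels must not exceed n_voxels")
    if (n_runs < 2L || n_runs %% 2L != 0L)
      stop("n_runs must be an even count >= 2 (odd/even split must exist)")
    if (prototype_spread <= 0) stop("prototype_spread must be positive")
    if (within_class_jitter < 0 || noise_sd < 0 || subject_gain_sd < 0)
      stop("all noise scales must be nonnegative")
    if (min(n_classes, n_subjects, n_voxels, d0, d1) < 1L)
      stop("counts and dimensions must be positive")
  })
  structure(cfg, class = "synthetic_config")
}

#' Run-noise level for a target split-half reliability
#'
#' Under the generative model, a planted voxel's response to a stimulus is
#' `gain * (w . y0) + noise`; with signal variance `s^2` across stimuli and
#' `n_runs/2` runs per half, the expected split-half correlation is
#' `r = s^2 / (s^2 + noise_sd^2 / (n_runs/2))`. This inverts that relation,
#' giving the `noise_sd` that plants voxels at a chosen true reliability.
#'
#' @param target_r desired expected split-half reliability in (0, 1).
#' @param prototype_spread the generator's between-class scale.
#' @param n_runs run count of the dataset.
#' @return the `noise_sd` to pass to [synthetic_config()].
#' @export
reliability_noise_sd <- function(target_r, prototype_spread = 1, n_runs = 8L) {
  stopifnot(target_r > 0, target_r < 1)
  prototype_spread * sqrt((n_runs / 2) * (1 - target_r) / target_r)
}

#' Generate a synthetic stimulus table and action-feature space
#'
#' Rows of `y0` are class prototypes plus within-class jitter; `y1` is a
#' fixed random linear image of `y0` plus small noise (so the auxiliary
#' loss term is informative about the primary target); the softmax readout
#' stacks the class prototypes as rows of `W` with zero bias, making each
#' prototype its own nearest readout direction.
#'
#' @param config a `synthetic_config`.
#' @return list with elements `table` (a `stimulus_table`) and `space`
#'   (an `action_feature_space`).
#' @export
generate_feature_space <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, 1L), {
    C <- config$n_classes
    m <- config$n_stimuli_per_class
    d0 <- config$d0; d1 <- config$d1
    proto <- matrix(rnorm(C * d0, sd = config$prototype_spread), C, d0)
    category <- rep(seq_len(C), each = m)
    y0 <- proto[category, , drop = FALSE] +
      matrix(rnorm(C * m * d0, sd = config$within_class_jitter), C * m, d0)
    A <- matrix(rnorm(d1 * d0, sd = 1 / sqrt(d0)), d1, d0)
    y1 <- y0 %*% t(A) +
      matrix(rnorm(C * m * d1, sd = 0.05 * config$prototype_spread), C * m, d1)
    set_id <- if (m >= 2L) rep_len(c(1L, 2L), C * m) else rep(1L, C)
    table <- stimulus_table(
      stimulus_id = sprintf("stim%03d", seq_len(C * m)),
      category = category, set_id = set_id)
    space <- action_feature_space(y0 = y0, y1 = y1, W = proto,
                                  b = rep(0, C),
                                  stimulus_id = table$stimulus_id)
    list(table = table, space = space)
  })
}

#' Generate multi-subject beta maps with a planted linear encoding
#'
#' Each planted ("reliable") voxel `v` responds to stimulus `i` in run `t`
#' of subject `s` as `gain_s * (w_v . y0_i) + noise`, with `w_v` a fixed
#' random encoding vector shared across subjects and runs; the remaining
#' voxels are pure run noise. Encoding vectors have entries of sd
#' `1/sqrt(d0)`, so the signal variance across stimuli is approximately
#' `prototype_spread^2` regardless of the feature dimension.
#'
#' @param space the `action_feature_space` from [generate_feature_space()].
#' @param table the matching `stimulus_table`.
#' @param config the same `synthetic_config`.
#' @return list with elements `betas` (list of `subject_betas`) and
#'   `ground_truth` (list: `reliable_idx`, `encoding` matrix d0 x
#'   n_reliable, `gains` per subject).
#' @export
generate_subject_betas <- function(space, table, config) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(space, "action_feature_space"))
  if (nrow(space$y0) != nrow(table))
    stop("feature space and stimulus table are inconsistent")
  if (config$n_runs < 2L) stop("n_runs < 2: no split-half possible")
  with_seed(derive_seed(config$seed, 2L), {
    nv <- config$n_voxels
    nr <- config$n_reliable_voxels
    ns <- nrow(table)
    reliable_idx <- sort(sample.int(nv, nr))
    enc <- matrix(rnorm(config$d0 * nr, sd = 1 / sqrt(config$d0)),
                  config$d0, nr)
    signal <- space$y0 %*% enc                      # stimuli x reliable
    gains <- 1 + rnorm(config$n_subjects, sd = config$subject_gain_sd)
    betas <- lapply(seq_len(config$n_subjects), function(s) {
      runs <- lapply(seq_len(config$n_runs), function(t) {
        m <- matrix(rnorm(ns * nv, sd = config$noise_sd), ns, nv)
        m[, reliable_idx] <- m[, reliable_idx] + gains[s] * signal
        m
      })
      names(runs) <- sprintf("run%d", seq_len(config$n_runs))
      subject_betas(sprintf("sub%02d", s), runs, table)
    })
    list(betas = betas,
         ground_truth = list(reliable_idx = reliable_idx,
                             encoding = enc, gains = gains))
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_feature_space()] then
#' [generate_subject_betas()].
#'
#' @param config a `synthetic_config`.
#' @return list with `table`, `space`, `betas`, `ground_truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  fs <- generate_feature_space(config)
  sb <- generate_subject_betas(fs$space, fs$table, config)
  list(table = fs$table, space = fs$space, betas = sb$betas,
       ground_truth = sb$ground_truth, config = config)
}
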